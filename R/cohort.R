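# Cohort construction: index-drug report selection, mutually exclusive
# regimen classification via a drug-name lexicon, target-event flagging.

.REGIMEN_LEVELS <- c("MONO", "PLUS_CHEMO", "PLUS_ICI", "PLUS_TARGETED")
.DEFAULT_PRECEDENCE <- c("PLUS_CHEMO", "PLUS_ICI", "PLUS_TARGETED")

#' Normalize a free-text drug name
#'
#' Trims, collapses internal whitespace and case-folds.  Optionally strips
#' trailing dosage tokens such as `"100 mg"` (off by default, since lexicon
#' names never carry them).
#'
#' @param raw character vector of raw DRUGNAME values.
#' @param strip_dosage strip trailing `<number><unit>` tokens?
#' @return normalized character vector.
#' @examples
#' normalize_drugname("  AVASTIN ")   # "avastin"
#' @export
normalize_drugname <- function(raw, strip_dosage = FALSE) {
  x <- tolower(trimws(as.character(raw)))
  x <- gsub("\\s+", " ", x)
  if (strip_dosage) {
    pat <- "( [0-9]+(\\.[0-9]+)?\\s*(mg|mcg|ug|g|ml|iu|%))+$"
    x <- trimws(sub(pat, "", x))
  }
  x
}

#' Load a drug lexicon from a configuration file
#'
#' The file is INI-style with sections `[index]`, `[chemotherapy]`, `[ici]`,
#' `[targeted]` listing one drug name per line, and an optional
#' `[biosimilar_deny]` section of regex patterns.  All names are normalized
#' at load time; the index synonyms must be disjoint from the three
#' co-medication category sets.
#'
#' @param path configuration file; defaults to the packaged lexicon that
#'   reproduces the published bevacizumab regimen table.
#' @return an object of class `drug_lexicon`: list with character-set
#'   elements `index`, `chemotherapy`, `ici`, `targeted`, `biosimilar_deny`.
#' @export
read_drug_lexicon <- function(path = system.file("extdata", "bv_lexicon.cfg",
                                                 package = "faersignal")) {
  cfg <- read_config_file(path)
  need <- c("index", "chemotherapy", "ici", "targeted")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("lexicon missing section(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lex <- lapply(cfg[need], function(v) unique(normalize_drugname(v)))
  lex$biosimilar_deny <- if (!is.null(cfg$biosimilar_deny))
    tolower(trimws(cfg$biosimilar_deny)) else character(0)
  if (length(lex$index) == 0L)
    stop("lexicon has an empty [index] section", call. = FALSE)
  overlap <- intersect(lex$index,
                       c(lex$chemotherapy, lex$ici, lex$targeted))
  if (length(overlap))
    stop("index synonyms overlap co-medication categories: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  structure(lex, class = "drug_lexicon")
}

#' @rdname read_drug_lexicon
#' @export
default_lexicon <- function() read_drug_lexicon()

#' Packaged default target preferred terms
#'
#' @return character vector of target MedDRA preferred terms (lower-cased).
#' @export
default_target_pts <- function() {
  path <- system.file("extdata", "target_pts.txt", package = "faersignal")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  tolower(lines[nzchar(lines)])
}

# TRUE for drug names that are index synonyms and not on the biosimilar
# deny-list
.is_index_name <- function(norm_names, lexicon) {
  hit <- norm_names %in% lexicon$index
  for (pat in lexicon$biosimilar_deny)
    hit <- hit & !grepl(pat, norm_names)
  hit
}

#' Select index-drug reports
#'
#' Keeps reports carrying at least one drug whose normalized name exactly
#' equals an index synonym; names matching a biosimilar deny-list pattern
#' never qualify.  Matching is exact on the normalized name — substring
#' matching is deliberately avoided (it would conflate distinct molecules).
#'
#' @param drug a DRUG `data.table` with columns `primaryid`, `drugname`.
#' @param lexicon a [read_drug_lexicon()] object.
#' @param restrict_roles optional character vector of role codes (e.g.
#'   `c("PS","SS")`); when supplied, only drug rows with those roles count.
#' @return character vector of selected `primaryid`s (stable input order).
#' @export
select_index_reports <- function(drug, lexicon, restrict_roles = NULL) {
  if (!inherits(lexicon, "drug_lexicon") || length(lexicon$index) == 0L)
    stop("empty or invalid drug lexicon", call. = FALSE)
  drug <- as.data.table(drug)
  if (!is.null(restrict_roles) && "role_cod" %in% names(drug))
    drug <- drug[toupper(trimws(role_cod)) %in% toupper(restrict_roles)]
  norm <- normalize_drugname(drug$drugname)
  unique(drug$primaryid[.is_index_name(norm, lexicon)])
}

#' Classify index reports into mutually exclusive regimen subgroups
#'
#' Co-medication category membership is computed from normalized drug names;
#' when several categories co-occur, assignment follows the precedence
#' `PLUS_CHEMO > PLUS_ICI > PLUS_TARGETED` (configurable), falling back to
#' `MONO` when no co-medication category is present.  Classification is
#' invariant to drug order within a report.
#'
#' @param drug DRUG table (`primaryid`, `drugname`, optionally `role_cod`).
#' @param report_ids `primaryid`s of the index cohort to classify.
#' @param lexicon a [read_drug_lexicon()] object.
#' @param precedence character vector ordering the three combination
#'   classes; must be a permutation of `PLUS_CHEMO`, `PLUS_ICI`,
#'   `PLUS_TARGETED`.
#' @param restrict_roles optional role-code filter for co-medication rows.
#' @return factor of regimen classes (levels `MONO`, `PLUS_CHEMO`,
#'   `PLUS_ICI`, `PLUS_TARGETED`), one per `report_ids` element.
#' @export
classify_regimens <- function(drug, report_ids, lexicon,
                              precedence = .DEFAULT_PRECEDENCE,
                              restrict_roles = NULL) {
  if (!setequal(precedence, .DEFAULT_PRECEDENCE))
    stop("precedence must be a permutation of ",
         paste(.DEFAULT_PRECEDENCE, collapse = ", "), call. = FALSE)
  drug <- as.data.table(drug)[primaryid %in% report_ids]
  if (!is.null(restrict_roles) && "role_cod" %in% names(drug))
    drug <- drug[toupper(trimws(role_cod)) %in% toupper(restrict_roles)]
  drug[, norm := normalize_drugname(drugname)]
  catsets <- list(PLUS_CHEMO = lexicon$chemotherapy,
                  PLUS_ICI = lexicon$ici,
                  PLUS_TARGETED = lexicon$targeted)
  memb <- drug[, .(
    PLUS_CHEMO = any(norm %in% catsets$PLUS_CHEMO),
    PLUS_ICI = any(norm %in% catsets$PLUS_ICI),
    PLUS_TARGETED = any(norm %in% catsets$PLUS_TARGETED)
  ), by = primaryid]
  memb <- memb[match(report_ids, primaryid)]
  cls <- rep("MONO", length(report_ids))
  for (p in rev(precedence)) {
    has <- memb[[p]]
    has[is.na(has)] <- FALSE
    cls[has] <- p
  }
  factor(cls, levels = .REGIMEN_LEVELS)
}

#' Flag reports carrying a target adverse event
#'
#' Case-insensitive exact preferred-term matching; a report with several
#' target PTs is flagged once (report-level flag, set semantics).
#'
#' @param reac REAC table (`primaryid`, `pt`).
#' @param report_ids reports to flag.
#' @param target_pts non-empty character vector of target PTs.
#' @return logical vector along `report_ids`.
#' @export
flag_target_events <- function(reac, report_ids,
                               target_pts = default_target_pts()) {
  if (length(target_pts) == 0L)
    stop("target_pts must be non-empty", call. = FALSE)
  reac <- as.data.table(reac)
  tgt <- tolower(trimws(target_pts))
  hits <- unique(reac$primaryid[tolower(trimws(reac$pt)) %in% tgt])
  report_ids %in% hits
}

#' Build the analysis cohort from deduplicated tables
#'
#' Runs index-report selection, regimen classification and target-event
#' flagging over a deduplicated FAERS table set and assembles one row per
#' index report with its demographics.  Target-event flags for the full
#' deduplicated background (needed for the disproportionality contingency
#' tables) are returned alongside.
#'
#' @param tables a `faers_tables` list whose `demo` has already been
#'   deduplicated (see [faers_dedup()]).
#' @param lexicon a [read_drug_lexicon()] object.
#' @param target_pts target preferred terms.
#' @param precedence regimen precedence, see [classify_regimens()].
#' @param restrict_roles optional role-code filter for co-medication.
#' @return list with
#'   \describe{
#'     \item{cohort}{`data.table`, one row per index report: `primaryid`,
#'       `caseid`, `sex`, `occp_cod`, `reporter_country`, `fda_dt`,
#'       `event_dt`, `fda_year`, `regimen`, `is_target`.}
#'     \item{background}{`data.table` of all deduplicated reports with
#'       `primaryid` and `is_target`.}
#'   }
#' @export
build_cohort <- function(tables, lexicon = default_lexicon(),
                         target_pts = default_target_pts(),
                         precedence = .DEFAULT_PRECEDENCE,
                         restrict_roles = NULL) {
  demo <- as.data.table(tables$demo)
  drug <- as.data.table(tables$drug)
  reac <- as.data.table(tables$reac)

  idx <- select_index_reports(drug, lexicon, restrict_roles = NULL)
  idx <- idx[idx %in% demo$primaryid]

  background <- data.table(primaryid = demo$primaryid)
  background[, is_target := flag_target_events(reac, primaryid, target_pts)]

  cohort <- demo[primaryid %in% idx,
                 intersect(c("primaryid", "caseid", "sex", "occp_cod",
                             "reporter_country", "fda_dt", "event_dt"),
                           names(demo)),
                 with = FALSE]
  cohort[, regimen := classify_regimens(drug, primaryid, lexicon,
                                        precedence = precedence,
                                        restrict_roles = restrict_roles)]
  cohort[, is_target := flag_target_events(reac, primaryid, target_pts)]
  cohort[, fda_year := faers_parse_date(fda_dt)$year]

  # audit: every selected report must still carry the index drug
  stopifnot(all(cohort$primaryid %in% idx))
  list(cohort = cohort, background = background)
}
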
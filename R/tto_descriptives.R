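# Time-to-onset derivation and Table-style demographic/outcome summaries.

.ONSET_EXCLUSIONS <- c("partial_or_missing_event_date",
                       "partial_or_missing_start_date",
                       "event_before_start")

.DEFAULT_ONSET_BINS <- c(0, 30, 60, 90, 180, 360, Inf)

#' Derive time-to-onset records for the target-event cohort
#'
#' Onset is the calendar-day difference between the adverse-event start date
#' (DEMO `EVENT_DT`) and the therapy start date (THER `START_DT`) of the
#' earliest fully dated index-drug therapy entry.  Both dates must be full
#' (year, month, day); a same-day pair gives 0 days.  Exclusions are data,
#' not errors — each excluded report carries exactly one reason, the first
#' failing rule in the order: partial/missing event date, partial/missing
#' start date, event before start.
#'
#' @param cohort cohort table from [build_cohort()]; only rows with
#'   `is_target == TRUE` are used.
#' @param tables the (deduplicated) `faers_tables` providing `drug` and
#'   `ther`.
#' @param lexicon lexicon identifying index-drug rows.
#' @return `data.table` with one row per target-event report: `primaryid`,
#'   `regimen`, `onset_days` (integer, `NA` when excluded),
#'   `exclusion_reason` (`NA` when usable).
#' @export
compute_onset <- function(cohort, tables, lexicon = default_lexicon()) {
  cohort <- as.data.table(cohort)[is_target == TRUE]
  drug <- as.data.table(tables$drug)
  ther <- if (!is.null(tables$ther)) as.data.table(tables$ther) else
    data.table(primaryid = character(0), dsg_drug_seq = character(0),
               start_dt = character(0))

  out <- cohort[, .(primaryid, regimen, event_dt)]
  epd <- faers_parse_date(out$event_dt)
  out[, event_days := .date_to_days(epd)]

  # index-drug therapy rows: THER.dsg_drug_seq links DRUG.drug_seq
  idx_drug <- drug[.is_index_name(normalize_drugname(drugname),
                                  lexicon) & primaryid %in% out$primaryid,
                   .(primaryid, drug_seq)]
  idx_ther <- ther[idx_drug,
                   on = c(primaryid = "primaryid", dsg_drug_seq = "drug_seq"),
                   nomatch = NULL]
  if (nrow(idx_ther)) {
    spd <- faers_parse_date(idx_ther$start_dt)
    idx_ther[, start_days := .date_to_days(spd)]
    starts <- idx_ther[!is.na(start_days),
                       .(start_days = min(start_days)), by = primaryid]
  } else {
    starts <- data.table(primaryid = character(0), start_days = integer(0))
  }
  out <- starts[out, on = "primaryid"]

  out[, exclusion_reason := NA_character_]
  out[is.na(event_days), exclusion_reason := .ONSET_EXCLUSIONS[1L]]
  out[is.na(exclusion_reason) & is.na(start_days),
      exclusion_reason := .ONSET_EXCLUSIONS[2L]]
  out[is.na(exclusion_reason) & event_days < start_days,
      exclusion_reason := .ONSET_EXCLUSIONS[3L]]
  out[, onset_days := ifelse(is.na(exclusion_reason),
                             as.integer(event_days - start_days),
                             NA_integer_)]
  out[, .(primaryid, regimen, onset_days, exclusion_reason)]
}

#' Summarize time-to-onset
#'
#' Median and quartiles use linear interpolation between order statistics
#' (the common "type 7" quantile rule — recorded in the output so the
#' convention is auditable).  The cumulative curve is the empirical CDF over
#' the usable onset days; a per-bin percentage table over configurable day
#' bins is included.
#'
#' @param onset table from [compute_onset()].
#' @param group optional regimen level to filter on.
#' @param bins upper bin edges in days (right-closed; defaults to
#'   0–30, 31–60, 61–90, 91–180, 181–360, >360).
#' @param quantile_type quantile algorithm passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @return list of class `onset_summary`: `n_used`, `n_excluded`,
#'   `exclusions` (reason counts), `median_days`, `q1_days`, `q3_days`,
#'   `cdf` (`data.table` days / cum_frac), `bin_table`, `quantile_type`.
#'   When no usable record exists, an empty-summary marker with
#'   `n_used = 0` and `NA` statistics.
#' @export
summarize_onset <- function(onset, group = NULL,
                            bins = .DEFAULT_ONSET_BINS,
                            quantile_type = 7L) {
  onset <- as.data.table(onset)
  if (!is.null(group)) onset <- onset[regimen == group]
  used <- onset$onset_days[!is.na(onset$onset_days)]
  excl <- onset$exclusion_reason[!is.na(onset$exclusion_reason)]
  res <- list(n_used = length(used), n_excluded = length(excl),
              exclusions = table(factor(excl, levels = .ONSET_EXCLUSIONS)),
              quantile_type = as.integer(quantile_type))
  if (length(used) == 0L) {
    res$median_days <- res$q1_days <- res$q3_days <- NA_real_
    res$cdf <- data.table(days = numeric(0), cum_frac = numeric(0))
    res$bin_table <- data.table(bin = character(0), n = integer(0),
                                pct = numeric(0))
    return(structure(res, class = "onset_summary"))
  }
  qs <- stats::quantile(used, c(0.25, 0.5, 0.75), type = res$quantile_type,
                        names = FALSE)
  res$q1_days <- qs[1]; res$median_days <- qs[2]; res$q3_days <- qs[3]

  days <- sort(unique(used))
  res$cdf <- data.table(days = days,
                        cum_frac = vapply(days, function(d)
                          mean(used <= d), 0.0))

  lo <- head(bins, -1L); hi <- tail(bins, -1L)
  lab <- ifelse(is.finite(hi),
                sprintf("%g-%g", ifelse(lo == 0, 0, lo + 1), hi),
                sprintf(">%g", lo))
  cnt <- vapply(seq_along(hi), function(i)
    sum(used > lo[i] & used <= hi[i] | (lo[i] == 0 & used == 0)), 0L)
  res$bin_table <- data.table(bin = lab, n = cnt,
                              pct = round(100 * cnt / length(used), 1))
  structure(res, class = "onset_summary")
}

#' @export
print.onset_summary <- function(x, ...) {
  cat(sprintf("Time to onset: n = %d used, %d excluded\n",
              x$n_used, x$n_excluded))
  if (x$n_used > 0)
    cat(sprintf("  median %.1f days (IQR %.2f-%.2f)\n",
                x$median_days, x$q1_days, x$q3_days))
  invisible(x)
}

#' Default indication keyword map
#'
#' Ordered named list mapping summary categories to case-insensitive regex
#' keyword patterns applied to indication preferred terms.  A report's
#' category is the first matching entry; unmatched terms fall into
#' `Others`, absent indications into `Unspecified`.
#' @return named character vector (category -> regex).
#' @export
default_indication_map <- function() {
  c("Lung cancer"          = "lung|bronch|nsclc|sclc",
    "Colorectal cancer"    = "colorect|colon|rect[ au]|caecum|cecum",
    "Breast cancer"        = "breast",
    "Renal cancer"         = "renal|kidney",
    "Gastric cancer"       = "gastric|stomach",
    "Head and neck cancer" = "head and neck|laryn|pharyn|oral cavity",
    "Ovarian cancer"       = "ovar",
    "Uterus cancer"        = "uter|endometri|cervi",
    "Liver cancer"         = "liver|hepat")
}

.OUTCOME_LEVELS <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

.norm_sex <- function(x) {
  x <- toupper(trimws(x))
  ifelse(x == "F", "Female", ifelse(x == "M", "Male", "Unknown"))
}

.norm_reporter <- function(x) {
  x <- toupper(trimws(x))
  ifelse(x %in% c("MD", "PH", "CN", "HP", "OT"), x, "Unspecified")
}

.COUNTRY_MAP <- c(
  "US" = "United States", "USA" = "United States",
  "UNITED STATES" = "United States",
  "UNITED STATES OF AMERICA" = "United States",
  "JP" = "Japan", "JAPAN" = "Japan",
  "CN" = "China", "CHINA" = "China",
  "GB" = "United Kingdom", "UK" = "United Kingdom",
  "UNITED KINGDOM" = "United Kingdom",
  "DE" = "Germany", "GERMANY" = "Germany")

.norm_country <- function(x) {
  x <- toupper(trimws(x))
  out <- unname(.COUNTRY_MAP[x])
  out[is.na(out) & nzchar(x)] <- "Others"
  out[is.na(out)] <- "Unspecified"
  out
}

.year_bin <- function(year) {
  ifelse(is.na(year), "Unknown",
  ifelse(year <= 2008, "2008 and before",
  ifelse(year <= 2013, "2009-2013",
  ifelse(year <= 2018, "2014-2018", "2019-2023"))))
}

.map_indication <- function(pts, map) {
  # first matching category in map order, across all of the report's terms
  for (i in seq_along(map)) {
    if (any(grepl(map[[i]], pts, ignore.case = TRUE)))
      return(names(map)[i])
  }
  "Others"
}

.count_block <- function(cohort, characteristic, value_fn, groups) {
  vals <- value_fn(cohort)
  rows <- list()
  for (g in names(groups)) {
    sub <- vals[groups[[g]]]
    size <- sum(groups[[g]])
    tb <- table(sub)
    cats <- names(tb)
    if (is.null(cats)) cats <- character(0)
    rows[[g]] <- data.table(characteristic = rep(characteristic,
                                                 length(cats)),
                            category = cats, group = rep(g, length(cats)),
                            n = as.integer(tb),
                            pct = round(100 * as.integer(tb) /
                                          max(size, 1L), 1))
  }
  rbindlist(rows)
}

#' Demographic and outcome summary of the target-event cohort
#'
#' Produces counts and percentages (percent of subgroup size, one decimal)
#' per regimen subgroup and overall, for: gender, reporting-year bins
#' (from the FDA receipt year), indication categories (configurable keyword
#' map; unmatched terms to `Others`, absent to `Unspecified`), serious
#' outcome codes (non-exclusive — a report with several codes contributes to
#' each row; no outcome record gives `Unspecified`), reporter countries and
#' reporter occupations.  For single-valued characteristics, category counts
#' (including Unknown/Unspecified) sum exactly to the subgroup size.
#'
#' @param cohort target-event cohort rows (from [build_cohort()], filtered
#'   to `is_target`), with `regimen`, `sex`, `fda_year`, `occp_cod`,
#'   `reporter_country`.
#' @param outc OUTC table (`primaryid`, `outc_cod`) or `NULL`.
#' @param indi INDI table (`primaryid`, `indi_pt`) or `NULL`.
#' @param indication_map see [default_indication_map()].
#' @return `data.table` with columns `characteristic`, `category`, `group`
#'   (`Overall` or a regimen level), `n`, `pct`.
#' @export
summarize_cohort <- function(cohort, outc = NULL, indi = NULL,
                             indication_map = default_indication_map()) {
  cohort <- as.data.table(cohort)
  groups <- c(list(Overall = rep(TRUE, nrow(cohort))),
              lapply(setNames(.REGIMEN_LEVELS, .REGIMEN_LEVELS),
                     function(l) cohort$regimen == l))
  groups <- groups[vapply(groups, any, TRUE) | names(groups) == "Overall"]

  blocks <- list(
    .count_block(cohort, "Gender", function(d) .norm_sex(d$sex), groups),
    .count_block(cohort, "Reporting year",
                 function(d) .year_bin(d$fda_year), groups),
    .count_block(cohort, "Reported country",
                 function(d) .norm_country(d$reporter_country), groups),
    .count_block(cohort, "Reporter",
                 function(d) .norm_reporter(d$occp_cod), groups)
  )

  if (!is.null(indi)) {
    indi <- as.data.table(indi)[primaryid %in% cohort$primaryid &
                                  nzchar(trimws(indi_pt))]
    icat <- indi[, .(category = .map_indication(indi_pt, indication_map)),
                 by = primaryid]
    cat_by_id <- setNames(icat$category, icat$primaryid)
    blocks <- c(blocks, list(.count_block(
      cohort, "Indication",
      function(d) {
        v <- unname(cat_by_id[d$primaryid])
        v[is.na(v)] <- "Unspecified"
        v
      }, groups)))
  }

  if (!is.null(outc)) {
    outc <- as.data.table(outc)[primaryid %in% cohort$primaryid]
    outc[, code := toupper(trimws(outc_cod))]
    outc <- outc[code %in% .OUTCOME_LEVELS]
    rows <- list()
    for (g in names(groups)) {
      ids <- cohort$primaryid[groups[[g]]]
      size <- length(ids)
      if (size == 0L) {
        rows[[g]] <- data.table(characteristic = character(0),
                                category = character(0),
                                group = character(0), n = integer(0),
                                pct = numeric(0))
        next
      }
      sub <- unique(outc[primaryid %in% ids, .(primaryid, code)])
      tb <- table(factor(sub$code, levels = .OUTCOME_LEVELS))
      tb <- tb[tb > 0 | names(tb) %in% c("DE", "LT", "HO", "DS", "OT")]
      unspec <- size - length(unique(sub$primaryid))
      rows[[g]] <- data.table(
        characteristic = "Serious outcome",
        category = c(names(tb), "Unspecified"),
        group = g,
        n = c(as.integer(tb), as.integer(unspec)),
        pct = round(100 * c(as.integer(tb), unspec) / size, 1))
    }
    blocks <- c(blocks, list(rbindlist(rows)))
  }

  rbindlist(blocks)
}
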
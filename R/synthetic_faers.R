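# Synthetic FAERS generator.  Emits quarterly file sets in the same "$"
# dialect the reader consumes, with a known ground-truth association
# structure: per drug-group odds multipliers, injected duplicate case
# versions, partial/missing dates, free-text drug-name noise.

.NOISE_DRUGS <- c("Aspirin", "Metformin", "Omeprazole", "Lisinopril",
                  "Paracetamol", "Ibuprofen", "Atorvastatin",
                  "Levothyroxine", "Metoprolol", "Amlodipine")
.NOISE_PTS <- c("Nausea", "Headache", "Fatigue", "Pyrexia", "Epistaxis",
                "Rash", "Diarrhoea", "Vomiting", "Dizziness", "Anaemia")
.TARGET_PTS_EMIT <- c("Pulmonary haemorrhage", "Haemoptysis")
.INDI_POOL <- c("Non-small cell lung cancer", "Lung neoplasm malignant",
                "Colorectal cancer", "Breast cancer",
                "Renal cell carcinoma", "Gastric cancer", "Ovarian cancer",
                "Hepatocellular carcinoma", "Glioblastoma",
                "Cervix carcinoma")

#' Describe one synthetic drug-exposure group
#'
#' @param name group name; the names `index`, `chemo`, `ici`, `targeted`
#'   additionally drive the ground-truth regimen assignment.
#' @param drugs drug-name pool the group emits.
#' @param marginal_prob probability a report carries this group.
#' @param multiplier true odds multiplier for the target event
#'   (`>= 0`; 1 = no association).
#' @return a `sim_group` list.
#' @export
sim_group <- function(name, drugs, marginal_prob, multiplier = 1) {
  structure(list(name = name, drugs = drugs,
                 marginal_prob = marginal_prob, multiplier = multiplier),
            class = "sim_group")
}

.default_group_specs <- function() {
  lex <- default_lexicon()
  list(
    sim_group("index", c("Bevacizumab", "Avastin"), 0.10, 4),
    sim_group("chemo", c("Carboplatin", "Paclitaxel", "Cisplatin",
                         "Gemcitabine", "Fluorouracil", "Irinotecan"),
              0.30, 1),
    sim_group("ici", c("Atezolizumab", "Nivolumab", "Pembrolizumab"),
              0.05, 1),
    sim_group("targeted", c("Erlotinib", "Cetuximab", "Sorafenib",
                            "Trastuzumab"), 0.08, 1)
  )
}

.check_prob <- function(x, field, open0 = FALSE, open1 = TRUE) {
  bad <- !is.numeric(x) || length(x) != 1L || is.na(x) ||
    (open0 && x <= 0) || (!open0 && x < 0) ||
    (open1 && x >= 1) || (!open1 && x > 1)
  if (bad)
    stop(sprintf("invalid simulation config: %s must be a probability%s",
                 field,
                 if (open0) " in (0,1)" else " in [0,1)"), call. = FALSE)
}

#' Build and validate a simulation configuration
#'
#' The defaults describe the world the downstream analysis is designed for:
#' a background of spontaneous reports with a modest target-event rate, an
#' index-drug group carrying a true odds multiplier of 4 (the order of
#' magnitude the disproportionality analysis is meant to detect), a
#' duplicate-case fraction of 15% (the approximate share of FAERS report
#' versions removed by deduplication), roughly 30% partial and 30% missing
#' event dates (about half of real target-event reports lack a computable
#' onset), and a right-skewed log-normal onset with median 43 days and
#' geometric dispersion 4.5.
#'
#' @param n_reports number of unique reports (>= 1).
#' @param baseline_event_prob target-event probability for a report carrying
#'   no multiplier group, in (0,1).
#' @param group_specs list of [sim_group()] objects.
#' @param duplicate_rate fraction of cases re-emitted as a later version
#'   with the same CASEID, in [0,1).
#' @param partial_date_rate fraction of START_DT/EVENT_DT values truncated
#'   to `YYYYMM` or `YYYY`, in [0,1).
#' @param missing_event_date_rate fraction of EVENT_DT values blanked,
#'   in [0,1).
#' @param onset_median_days,onset_dispersion log-normal onset parameters:
#'   median (days, > 0) and geometric standard deviation (> 1).
#' @param outcome_probs named categorical distribution over outcome codes
#'   per report; the name `none` means no outcome record.
#' @param quarters character vector of quarter labels (`"2020q1"` style);
#'   reports are laid out in contiguous slices across them.
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
faers_sim_config <- function(n_reports = 5000,
                             baseline_event_prob = 0.02,
                             group_specs = .default_group_specs(),
                             duplicate_rate = 0.15,
                             partial_date_rate = 0.30,
                             missing_event_date_rate = 0.30,
                             onset_median_days = 43,
                             onset_dispersion = 4.5,
                             outcome_probs = c(DE = 0.20, LT = 0.02,
                                               HO = 0.20, DS = 0.01,
                                               OT = 0.30, none = 0.27),
                             quarters = c("2020q1", "2020q2", "2020q3",
                                          "2020q4", "2021q1", "2021q2",
                                          "2021q3", "2021q4"),
                             seed = 20230401L) {
  if (!is.numeric(n_reports) || length(n_reports) != 1L ||
      is.na(n_reports) || n_reports < 1)
    stop("invalid simulation config: n_reports must be >= 1", call. = FALSE)
  .check_prob(baseline_event_prob, "baseline_event_prob", open0 = TRUE)
  .check_prob(duplicate_rate, "duplicate_rate")
  .check_prob(partial_date_rate, "partial_date_rate")
  .check_prob(missing_event_date_rate, "missing_event_date_rate")
  if (!is.numeric(onset_median_days) || onset_median_days <= 0)
    stop("invalid simulation config: onset_median_days must be > 0",
         call. = FALSE)
  if (!is.numeric(onset_dispersion) || onset_dispersion <= 1)
    stop("invalid simulation config: onset_dispersion must be > 1",
         call. = FALSE)
  if (length(group_specs) == 0L)
    stop("invalid simulation config: group_specs must be non-empty",
         call. = FALSE)
  for (g in group_specs) {
    if (!inherits(g, "sim_group"))
      stop("invalid simulation config: group_specs entries must be sim_group",
           call. = FALSE)
    .check_prob(g$marginal_prob,
                sprintf("group_specs[%s]$marginal_prob", g$name),
                open0 = TRUE)
    if (!is.numeric(g$multiplier) || g$multiplier < 0)
      stop(sprintf(
        "invalid simulation config: group_specs[%s]$multiplier must be >= 0",
        g$name), call. = FALSE)
  }
  if (anyDuplicated(vapply(group_specs, `[[`, "", "name")))
    stop("invalid simulation config: group_specs names must be unique",
         call. = FALSE)
  if (abs(sum(outcome_probs) - 1) > 1e-8 || any(outcome_probs < 0))
    stop("invalid simulation config: outcome_probs must be a distribution",
         call. = FALSE)
  if (!all(grepl("^[0-9]{4}q[1-4]$", quarters)))
    stop("invalid simulation config: quarters must look like '2020q1'",
         call. = FALSE)
  structure(list(n_reports = as.integer(n_reports),
                 baseline_event_prob = baseline_event_prob,
                 group_specs = group_specs,
                 duplicate_rate = duplicate_rate,
                 partial_date_rate = partial_date_rate,
                 missing_event_date_rate = missing_event_date_rate,
                 onset_median_days = onset_median_days,
                 onset_dispersion = onset_dispersion,
                 outcome_probs = outcome_probs,
                 quarters = quarters,
                 seed = as.integer(seed)),
            class = "sim_config")
}

.quarter_bounds <- function(q) {
  y <- as.integer(substr(q, 1, 4))
  qi <- as.integer(substr(q, 6, 6))
  start <- as.Date(sprintf("%04d-%02d-01", y, (qi - 1) * 3 + 1))
  end <- seq(start, by = "3 months", length.out = 2)[2] - 1
  c(as.integer(start), as.integer(end))
}

.fmt_date <- function(days) format(as.Date(days, origin = "1970-01-01"),
                                   "%Y%m%d")

.mangle_name <- function(x) {
  style <- sample.int(3L, length(x), replace = TRUE)
  out <- x
  out[style == 1L] <- toupper(out[style == 1L])
  out[style == 2L] <- tolower(out[style == 2L])
  pad <- runif(length(out)) < 0.1
  out[pad] <- paste0(out[pad], " ")
  out
}

.truncate_dates <- function(dt, rate) {
  has <- nzchar(dt)
  hit <- has & runif(length(dt)) < rate
  kind <- runif(length(dt)) < 0.5
  dt[hit & kind] <- substr(dt[hit & kind], 1, 6)
  dt[hit & !kind] <- substr(dt[hit & !kind], 1, 4)
  dt
}

#' Simulate FAERS-shaped tables with ground truth
#'
#' Pure in-memory counterpart of [faers_generate()]: returns the record
#' tables and the ground truth without touching disk.  Event assignment for
#' a report carrying groups G uses odds
#' `baseline_odds * prod(multiplier(g), g in G)`.  Deterministic given the
#' config seed.
#'
#' @param config a [faers_sim_config()] object.
#' @return list with `tables` (a `faers_tables`-shaped list of
#'   `data.table`s: demo, drug, reac, ther, outc, indi) and `truth`
#'   (class `faers_truth`): per unique report its CASEID, surviving
#'   PRIMARYID, group flags, event flag, onset days and regimen, plus the
#'   configured multipliers.
#' @export
faers_simulate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_reports
  gs <- config$group_specs
  gnames <- vapply(gs, `[[`, "", "name")

  # group membership and event assignment
  memb <- vapply(gs, function(g) runif(n) < g$marginal_prob,
                 logical(n))
  memb <- matrix(memb, nrow = n,
                 dimnames = list(NULL, gnames))
  mult <- rep(1, n)
  for (j in seq_along(gs))
    mult <- mult * ifelse(memb[, j], gs[[j]]$multiplier, 1)
  base_odds <- config$baseline_event_prob / (1 - config$baseline_event_prob)
  odds <- base_odds * mult
  p_event <- odds / (1 + odds)
  event <- runif(n) < p_event

  # regimen ground truth (only meaningful for index-carrying reports)
  regimen <- rep(NA_character_, n)
  if ("index" %in% gnames) {
    idx <- memb[, "index"]
    regimen[idx] <- "MONO"
    if ("targeted" %in% gnames) regimen[idx & memb[, "targeted"]] <- "PLUS_TARGETED"
    if ("ici" %in% gnames) regimen[idx & memb[, "ici"]] <- "PLUS_ICI"
    if ("chemo" %in% gnames) regimen[idx & memb[, "chemo"]] <- "PLUS_CHEMO"
  }

  # ids, quarters (contiguous slices), receipt dates
  caseid <- sprintf("C%07d", seq_len(n))
  primaryid <- as.character(seq_len(n) * 10 + 1)
  qb <- vapply(config$quarters, .quarter_bounds, integer(2))
  slice <- sort(rep_len(seq_along(config$quarters), n))
  fda_days <- qb[1, slice] +
    floor(runif(n) * (qb[2, slice] - qb[1, slice] + 1))

  # therapy start, onset, event date
  start_days <- fda_days - (60L + floor(runif(n) * 370))
  onset <- pmax(0L, as.integer(round(rlnorm(
    n, meanlog = log(config$onset_median_days),
    sdlog = log(config$onset_dispersion)))))
  event_days <- start_days + onset

  # drug rows: one per carried group plus 1-3 background drugs
  drug_rows <- list()
  for (j in seq_along(gs)) {
    rows <- which(memb[, j])
    if (!length(rows)) next
    drug_rows[[gnames[j]]] <- data.table(
      row = rows,
      drugname = sample(gs[[j]]$drugs, length(rows), replace = TRUE),
      role_cod = if (gnames[j] == "index") "PS" else
        sample(c("SS", "C"), length(rows), replace = TRUE))
  }
  nbg <- 1L + floor(runif(n) * 3)
  bg <- data.table(row = rep(seq_len(n), nbg))
  bg[, drugname := sample(.NOISE_DRUGS, .N, replace = TRUE)]
  bg[, role_cod := sample(c("SS", "C", "I"), .N, replace = TRUE)]
  drug <- rbindlist(c(drug_rows, list(bg)))
  setorder(drug, row)
  drug[, drug_seq := as.character(seq_len(.N)), by = row]
  drug[, drugname := .mangle_name(drugname)]

  # reactions: target PT for events, 1-2 noise PTs for everyone
  nnoise <- 1L + (runif(n) < 0.5)
  reac <- data.table(row = rep(seq_len(n), nnoise))
  reac[, pt := sample(.NOISE_PTS, .N, replace = TRUE)]
  if (any(event)) {
    tgt <- data.table(row = which(event),
                      pt = sample(.TARGET_PTS_EMIT, sum(event),
                                  replace = TRUE))
    reac <- rbind(reac, tgt)
  }
  setorder(reac, row)

  # therapy rows: index drugs start exactly at start_days; others jittered
  ther <- drug[, .(row, dsg_drug_seq = drug_seq, role_cod)]
  ther[, start := start_days[row]]
  is_idx <- .is_index_name(normalize_drugname(drug$drugname),
                           list(index = normalize_drugname(
                             unlist(lapply(gs[gnames == "index"],
                                           `[[`, "drugs"))),
                             biosimilar_deny = character(0)))
  ther[!is_idx, start := start + floor(runif(.N) * 21) - 10L]
  ther[, start_dt := .fmt_date(start)]

  # outcomes
  oc <- sample(names(config$outcome_probs), n, replace = TRUE,
               prob = config$outcome_probs)
  outc <- data.table(row = which(oc != "none"),
                     outc_cod = oc[oc != "none"])

  # indications (90% of reports, attached to drug_seq 1)
  has_indi <- runif(n) < 0.9
  indi <- data.table(row = which(has_indi),
                     indi_drug_seq = "1",
                     indi_pt = sample(.INDI_POOL, sum(has_indi),
                                      replace = TRUE))

  # assemble DEMO with noisy dates
  event_dt <- .fmt_date(event_days)
  event_dt[runif(n) < config$missing_event_date_rate] <- ""
  event_dt <- .truncate_dates(event_dt, config$partial_date_rate)
  demo <- data.table(
    primaryid = primaryid, caseid = caseid,
    fda_dt = .fmt_date(fda_days), event_dt = event_dt,
    sex = sample(c("F", "M", ""), n, replace = TRUE,
                 prob = c(0.35, 0.43, 0.22)),
    occp_cod = sample(c("MD", "PH", "CN", "HP", "OT", ""), n,
                      replace = TRUE,
                      prob = c(0.50, 0.06, 0.10, 0.05, 0.21, 0.08)),
    reporter_country = sample(c("US", "JP", "CN", "GB", "DE", "FR", "IT",
                                ""), n, replace = TRUE,
                              prob = c(0.45, 0.13, 0.06, 0.05, 0.06, 0.08,
                                       0.07, 0.10)),
    age = "", age_cod = "",
    quarter = config$quarters[slice])
  start_noisy <- .truncate_dates(ther$start_dt, config$partial_date_rate)

  finish <- function(tab) {
    tab[, primaryid := primaryid[row]]
    tab[, row := NULL]
    setcolorder(tab, "primaryid")
    tab[]
  }
  drug_out <- finish(drug[, .(row, drug_seq, drugname, role_cod)])
  reac_out <- finish(copy(reac))
  ther_out <- finish(data.table(row = ther$row,
                                dsg_drug_seq = ther$dsg_drug_seq,
                                start_dt = start_noisy, end_dt = ""))
  outc_out <- finish(copy(outc))
  indi_out <- finish(copy(indi))

  # duplicate case versions: same CASEID and content, later FDA_DT,
  # higher PRIMARYID; the duplicate lands in the quarter of its FDA_DT
  n_dup <- floor(config$duplicate_rate * n)
  kept_primaryid <- primaryid
  if (n_dup > 0) {
    dup_rows <- sort(sample.int(n, n_dup))
    dup_pid <- as.character(dup_rows * 10 + 2)
    dup_fda <- fda_days[dup_rows] + 10L + floor(runif(n_dup) * 91)
    last_end <- qb[2, ncol(qb)]
    dup_fda <- pmin(dup_fda, last_end)
    dup_q <- vapply(dup_fda, function(d)
      config$quarters[max(which(qb[1, ] <= d))], "")
    dup_demo <- copy(demo[dup_rows])
    dup_demo[, `:=`(primaryid = dup_pid, fda_dt = .fmt_date(dup_fda),
                    quarter = dup_q)]
    demo <- rbind(demo, dup_demo)
    reissue <- function(tab) {
      sub <- tab[primaryid %in% kept_primaryid[dup_rows]]
      sub[, primaryid := dup_pid[match(primaryid,
                                       kept_primaryid[dup_rows])]]
      rbind(tab, sub)
    }
    drug_out <- reissue(drug_out)
    reac_out <- reissue(reac_out)
    ther_out <- reissue(ther_out)
    outc_out <- reissue(outc_out)
    indi_out <- reissue(indi_out)
    kept_primaryid[dup_rows] <- dup_pid
  }

  truth <- data.table(caseid = caseid,
                      primaryid = kept_primaryid,
                      event = event, onset_days = onset,
                      regimen = regimen)
  for (g in gnames) truth[, (paste0("in_", g)) := memb[, g]]
  truth <- structure(list(reports = truth,
                          multipliers = setNames(
                            vapply(gs, `[[`, 0.0, "multiplier"), gnames),
                          n_duplicates = n_dup),
                     class = "faers_truth")

  tables <- structure(list(demo = demo, drug = drug_out, reac = reac_out,
                           ther = ther_out, outc = outc_out,
                           indi = indi_out),
                      class = "faers_tables")
  list(tables = tables, truth = truth)
}

#' Generate a synthetic FAERS quarterly file set on disk
#'
#' Runs [faers_simulate()] and writes one `"$"`-delimited file per dataset
#' and quarter (`DEMO2020q1.txt`, ...), in the dialect [faers_read_quarter()]
#' consumes.  Byte-identical across runs with the same config.
#'
#' @param config a [faers_sim_config()].
#' @param dir output directory (created if needed).
#' @return the ground truth (`faers_truth`), invisibly with attribute
#'   `files` listing what was written.
#' @export
faers_generate <- function(config, dir) {
  sim <- faers_simulate(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  demo <- sim$tables$demo
  qmap <- setNames(demo$quarter, demo$primaryid)
  written <- character(0)
  for (ds in names(sim$tables)) {
    tab <- copy(sim$tables[[ds]])
    tab[, .q := qmap[primaryid]]
    if ("quarter" %in% names(tab)) tab[, quarter := NULL]
    for (q in config$quarters) {
      sub <- tab[.q == q][, .q := NULL]
      if (nrow(sub) == 0L) next
      path <- file.path(dir, sprintf("%s%s.txt", toupper(ds), q))
      fwrite(sub, path, sep = "$", quote = FALSE, eol = "\n")
      written <- c(written, path)
    }
  }
  invisible(structure(sim$truth, files = written))
}

#' Realized odds ratio of a group in the generated unique reports
#'
#' Computed from the realized 2x2 of the generated unique reports (group
#' membership vs target event), not from the configured multiplier.
#'
#' @param truth a `faers_truth` object.
#' @param group group name.
#' @return the realized odds ratio, or `NA` with a warning when a margin is
#'   empty (undefined odds ratio).
#' @export
truth_odds_ratio <- function(truth, group) {
  stopifnot(inherits(truth, "faers_truth"))
  col <- paste0("in_", group)
  if (!col %in% names(truth$reports))
    stop("unknown group: ", group, call. = FALSE)
  g <- truth$reports[[col]]
  e <- truth$reports$event
  a <- sum(g & e); b <- sum(g & !e); c <- sum(!g & e); d <- sum(!g & !e)
  if (b == 0 || c == 0) {
    warning("realized odds ratio undefined: empty margin", call. = FALSE)
    return(NA_real_)
  }
  (a * d) / (b * c)
}

#' @export
print.faers_truth <- function(x, ...) {
  cat(sprintf("<faers_truth> %d unique reports, %d duplicate versions\n",
              nrow(x$reports), x$n_duplicates))
  cat("  multipliers:",
      paste(sprintf("%s=%g", names(x$multipliers), x$multipliers),
            collapse = ", "), "\n")
  invisible(x)
}
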
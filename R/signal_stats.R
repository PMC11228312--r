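# Disproportionality statistics: 2x2 contingency tables, reporting odds
# ratio (ROR) with normal-approximation confidence interval on the log
# scale, the positive-signal rule, and Pearson chi-square subgroup
# comparison.

#' Build a 2x2 disproportionality contingency table
#'
#' Counts unique reports:
#' `a` = group reports with the target event, `b` = group reports without,
#' `c` = background-minus-group reports with the event, `d` = the remainder,
#' so `a+b+c+d` equals the analysis population size.  The counting unit is
#' the unique deduplicated report throughout.
#'
#' @param group_ids `primaryid`s of the drug group of interest (must be a
#'   subset of the background).
#' @param background `data.table` with columns `primaryid`, `is_target` —
#'   the full deduplicated report set with target-event flags (see
#'   [build_cohort()]).
#' @return object of class `contingency_2x2`: named integer list
#'   `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(group_ids, background) {
  background <- as.data.table(background)
  group_ids <- unique(group_ids)
  if (!all(group_ids %in% background$primaryid))
    stop("group contains reports absent from the background set",
         call. = FALSE)
  ing <- background$primaryid %in% group_ids
  ev <- as.logical(background$is_target)
  out <- list(a = sum(ing & ev), b = sum(ing & !ev),
              c = sum(!ing & ev), d = sum(!ing & !ev))
  structure(lapply(out, as.integer), class = "contingency_2x2")
}

#' Reporting odds ratio with 95\% confidence interval and signal flag
#'
#' `ROR = (a*d)/(b*c)`; the confidence interval is
#' `exp(log(ROR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with `z = 1.96`.
#' A positive signal of disproportionate reporting requires the lower CI
#' limit to exceed 1 with at least three cases (`a >= 3`).  Any zero cell
#' makes the result non-estimable (no continuity correction by default; the
#' Haldane–Anscombe +0.5 correction is available behind `haldane`).
#'
#' @param t a `contingency_2x2` or a list/vector with `a`,`b`,`c`,`d`.
#' @param z normal quantile for the CI (1.96 as conventionally printed).
#' @param haldane add 0.5 to every cell before estimation?
#' @return object of class `signal_result`: list with `ror`, `ci_low`,
#'   `ci_high`, `n_cases`, `is_signal`, `z_quantile`, `estimable`.
#' @examples
#' compute_ror(list(a = 20, b = 80, c = 100, d = 9800))  # ROR 24.5
#' @export
compute_ror <- function(t, z = 1.96, haldane = FALSE) {
  cells <- as.numeric(c(t$a, t$b, t$c, t$d))
  if (length(cells) != 4L || anyNA(cells) || any(cells < 0))
    stop("contingency table must have nonnegative cells a, b, c, d",
         call. = FALSE)
  n_cases <- as.integer(t$a)
  if (haldane) cells <- cells + 0.5
  if (any(cells == 0)) {
    res <- list(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                n_cases = n_cases, is_signal = FALSE, z_quantile = z,
                estimable = FALSE)
    return(structure(res, class = "signal_result"))
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  ci <- exp(log(ror) + c(-1, 1) * z * se)
  res <- list(ror = ror, ci_low = ci[1], ci_high = ci[2],
              n_cases = n_cases,
              is_signal = ci[1] > 1 && n_cases >= 3L,
              z_quantile = z, estimable = TRUE)
  structure(res, class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("ROR: non-estimable (zero cell), n = %d\n", x$n_cases))
  } else {
    cat(sprintf("ROR %.2f [95%% CI %.2f-%.2f], n = %d, signal: %s\n",
                x$ror, x$ci_low, x$ci_high, x$n_cases,
                ifelse(x$is_signal, "yes", "no")))
  }
  invisible(x)
}

#' Chi-square comparison of event proportions between two drug groups
#'
#' Pearson chi-square (1 df, no continuity correction by default) on the
#' 2x2 formed by the `(a, b)` rows of two groups — event versus non-event
#' within each group.  The groups must be disjoint subsets of the same
#' background.  An expected cell below 1 attaches a warning flag to the
#' result rather than failing.
#'
#' @param tA,tB `contingency_2x2` tables for the two groups.
#' @param correct apply the Yates continuity correction?
#' @return list with `chi2`, `p_value`, `df`, `low_expected` (logical),
#'   `correct`.
#' @export
compare_groups <- function(tA, tB, correct = FALSE) {
  m <- rbind(c(tA$a, tA$b), c(tB$a, tB$b))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate comparison: a group or event margin is empty",
         call. = FALSE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  res <- list(chi2 = unname(ht$statistic), p_value = unname(ht$p.value),
              df = unname(ht$parameter),
              low_expected = any(expected < 1), correct = correct)
  if (res$low_expected)
    warning("expected cell count below 1 in subgroup comparison",
            call. = FALSE)
  res
}

#' Pair-level 2x2 contingency table (sensitivity mode)
#'
#' Alternative counting unit for sensitivity analysis: the unique
#' (report, preferred term) pair rather than the unique report.  `a` counts
#' target-PT pairs of group reports, `b` their non-target pairs, `c`/`d`
#' likewise outside the group.
#'
#' @param group_ids group `primaryid`s (subset of `background_ids`).
#' @param background_ids all deduplicated report ids.
#' @param reac REAC table (`primaryid`, `pt`).
#' @param target_pts target preferred terms.
#' @return `contingency_2x2`.
#' @export
build_contingency_pairs <- function(group_ids, background_ids, reac,
                                    target_pts = default_target_pts()) {
  group_ids <- unique(group_ids)
  if (!all(group_ids %in% background_ids))
    stop("group contains reports absent from the background set",
         call. = FALSE)
  reac <- as.data.table(reac)
  pairs <- unique(reac[primaryid %in% background_ids,
                       .(primaryid, pt = tolower(trimws(pt)))])
  pairs <- pairs[nzchar(pt)]
  ing <- pairs$primaryid %in% group_ids
  ev <- pairs$pt %in% tolower(trimws(target_pts))
  out <- list(a = sum(ing & ev), b = sum(ing & !ev),
              c = sum(!ing & ev), d = sum(!ing & !ev))
  structure(lapply(out, as.integer), class = "contingency_2x2")
}

#' Disproportionality analysis over regimen subgroups
#'
#' Convenience wrapper building one contingency table and ROR per regimen
#' subgroup (plus the whole index cohort) against the full deduplicated
#' background.
#'
#' @param cohort cohort table from [build_cohort()].
#' @param background background flag table from [build_cohort()].
#' @param z CI quantile.
#' @param unit counting unit: `"report"` (unique deduplicated report,
#'   default) or `"pair"` (unique report-PT pair, sensitivity mode;
#'   requires `reac`).
#' @param reac REAC table, needed for `unit = "pair"`.
#' @param target_pts target preferred terms, for `unit = "pair"`.
#' @return `data.table` with one row per group: `group`, `a`, `b`, `c`,
#'   `d`, `ror`, `ci_low`, `ci_high`, `n_cases`, `is_signal`.
#' @export
signal_table <- function(cohort, background, z = 1.96,
                         unit = c("report", "pair"), reac = NULL,
                         target_pts = default_target_pts()) {
  unit <- match.arg(unit)
  if (unit == "pair" && is.null(reac))
    stop("unit = 'pair' requires the REAC table", call. = FALSE)
  cohort <- as.data.table(cohort)
  groups <- c(list(ALL = cohort$primaryid),
              split(cohort$primaryid, cohort$regimen))
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    ct <- if (unit == "report") build_contingency(ids, background)
          else build_contingency_pairs(ids, background$primaryid, reac,
                                       target_pts)
    sr <- compute_ror(ct, z = z)
    data.table(group = g, a = ct$a, b = ct$b, c = ct$c, d = ct$d,
               ror = sr$ror, ci_low = sr$ci_low, ci_high = sr$ci_high,
               n_cases = sr$n_cases, is_signal = sr$is_signal)
  })
  rbindlist(rows)
}
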
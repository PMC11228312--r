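# Deduplication of case versions, per the FDA-recommended rule used with
# public FAERS extracts: within a CASEID keep the report with the latest
# FDA receipt date (FDA_DT); on ties keep the highest PRIMARYID.

# PRIMARYID comparator: numeric when every id in scope parses as a number,
# lexicographic otherwise.  FAERS PRIMARYIDs are numeric strings, but the
# comparator must not fall over on arbitrary keys.
.pid_rank <- function(pid) {
  num <- suppressWarnings(as.numeric(pid))
  if (!anyNA(num)) return(frank(num, ties.method = "dense"))
  frank(pid, ties.method = "dense")
}

#' Deduplicate a DEMO table by CASEID / FDA_DT / PRIMARYID
#'
#' Per CASEID keeps the record with the latest FDA_DT; among ties on
#' (CASEID, FDA_DT), keeps the highest PRIMARYID (numeric comparison when
#' all ids parse as numbers, lexicographic otherwise).  Records whose
#' FDA_DT does not yield at least a year are routed to an "undated" bin and
#' kept only if their CASEID has no dated record; such keeps are flagged in
#' the decision log.  Partial FDA_DT values sort below any more complete
#' date of the same year/month.  Only exact CASEID matches are merged; no
#' fuzzy matching across different CASEIDs is attempted.
#'
#' @param demo a `data.table`/`data.frame` with character columns
#'   `primaryid`, `caseid`, `fda_dt`.
#' @return a list with elements
#'   \describe{
#'     \item{kept}{the input rows that survive, one per CASEID, in CASEID
#'       order (deterministic).}
#'     \item{decisions}{a `data.table` with one row per CASEID: `caseid`,
#'       `kept_primaryid`, `dropped_primaryids` (comma-joined, `""` if
#'       none), `undated_keep` (logical).}
#'   }
#' @export
faers_dedup <- function(demo) {
  demo <- as.data.table(demo)
  need <- c("primaryid", "caseid", "fda_dt")
  miss <- setdiff(need, names(demo))
  if (length(miss))
    stop("faers_dedup: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  work <- copy(demo)
  pd <- faers_parse_date(work$fda_dt)
  work[, `:=`(.fda_key = .date_sort_key(pd),
              .pid_rank = .pid_rank(work$primaryid),
              .src = seq_len(.N))]

  # dated records win over undated ones within a CASEID
  work[, .dated := !is.na(.fda_key)]
  work[is.na(.fda_key), .fda_key := -Inf]

  setorder(work, caseid, -.dated, -.fda_key, -.pid_rank, .src)
  kept_idx <- work[, .src[1L], by = caseid]
  setnames(kept_idx, "V1", ".src")

  decisions <- work[, .(
    kept_primaryid = primaryid[1L],
    dropped_primaryids = paste(primaryid[-1L], collapse = ","),
    undated_keep = !.dated[1L]
  ), by = caseid]
  setorder(decisions, caseid)

  kept <- demo[sort(kept_idx$.src)]
  kept <- kept[order(caseid)]
  list(kept = kept, decisions = decisions)
}

#' Write a deduplication decision log as a delimited audit file
#'
#' @param decisions the `decisions` table from [faers_dedup()].
#' @param path output file path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_dedup_log <- function(decisions, path) {
  fwrite(decisions, path, sep = "\t")
  invisible(path)
}
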
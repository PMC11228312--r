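# Independent oracles and fixture builders shared across tests.  Oracles are
# deliberately written as plain loops, separate from the package's
# vectorized/data.table implementations.

# ---- brute-force dedup oracle ----------------------------------------------
# Keep, per CASEID, the record with the latest FDA_DT (records without a
# parseable year lose to any dated record); ties broken by highest
# PRIMARYID (numeric iff every id in the table parses as a number).
oracle_dedup <- function(demo) {
  demo <- as.data.frame(demo, stringsAsFactors = FALSE)
  datekey <- function(s) {
    s <- trimws(s)
    if (!grepl("^[0-9]+$", s)) return(NA_real_)
    n <- nchar(s)
    y <- m <- d <- 0
    if (n == 4) y <- as.numeric(s)
    else if (n == 6) { y <- as.numeric(substr(s, 1, 4)); m <- as.numeric(substr(s, 5, 6)) }
    else if (n == 8) { y <- as.numeric(substr(s, 1, 4)); m <- as.numeric(substr(s, 5, 6)); d <- as.numeric(substr(s, 7, 8)) }
    else return(NA_real_)
    if (y < 1900 || y > 2100) return(NA_real_)
    if (m > 12) m <- 0
    if (m > 0 && d > 0 &&
        is.na(as.Date(sprintf("%04d-%02d-%02d", y, m, d), "%Y-%m-%d")))
      d <- 0
    if (m == 0) d <- 0
    y * 10000 + m * 100 + d
  }
  all_numeric <- !anyNA(suppressWarnings(as.numeric(demo$primaryid)))
  pid_gt <- function(p, q) {
    if (all_numeric) as.numeric(p) > as.numeric(q) else p > q
  }
  kept <- character(0)
  for (cid in sort(unique(demo$caseid))) {
    rows <- demo[demo$caseid == cid, ]
    keys <- vapply(rows$fda_dt, datekey, 0.0)
    dated <- !is.na(keys)
    cand <- if (any(dated)) rows[dated, , drop = FALSE] else rows
    keys <- if (any(dated)) keys[dated] else rep(0, nrow(rows))
    best <- 1L
    for (i in seq_len(nrow(cand))[-1]) {
      if (keys[i] > keys[best] ||
          (keys[i] == keys[best] &&
           pid_gt(cand$primaryid[i], cand$primaryid[best])))
        best <- i
    }
    kept <- c(kept, cand$primaryid[best])
  }
  sort(kept)
}

random_demo_table <- function(n, seed) {
  set.seed(seed)
  caseids <- sprintf("K%02d", sample.int(max(2L, n %/% 2L), n, replace = TRUE))
  dates <- sample(c("20200101", "20200301", "20200102", "202003", "2020",
                    "20191231", "abc", "", "20200229", "20190229"),
                  n, replace = TRUE)
  pids <- as.character(sample.int(10 * n, n))
  data.frame(primaryid = pids, caseid = caseids, fda_dt = dates,
             stringsAsFactors = FALSE)
}

# ---- independent ROR oracle ------------------------------------------------
oracle_ror <- function(a, b, c, d, z = 1.96) {
  lror <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = exp(lror), ci_low = exp(lror - z * se),
       ci_high = exp(lror + z * se))
}

# ---- minimal in-memory FAERS table set -------------------------------------
# demo/drug/reac/ther rows from compact per-report descriptions
make_tables <- function(reports) {
  demo <- drug <- reac <- ther <- outc <- indi <- list()
  for (r in reports) {
    pid <- r$primaryid
    demo[[pid]] <- data.frame(
      primaryid = pid, caseid = r$caseid %||% pid,
      fda_dt = r$fda_dt %||% "20200601", event_dt = r$event_dt %||% "",
      sex = r$sex %||% "", occp_cod = r$occp_cod %||% "",
      reporter_country = r$country %||% "", stringsAsFactors = FALSE)
    dn <- r$drugs %||% character(0)
    if (length(dn))
      drug[[pid]] <- data.frame(primaryid = pid,
                                drug_seq = as.character(seq_along(dn)),
                                drugname = dn, role_cod = "PS",
                                stringsAsFactors = FALSE)
    pts <- r$pts %||% character(0)
    if (length(pts))
      reac[[pid]] <- data.frame(primaryid = pid, pt = pts,
                                stringsAsFactors = FALSE)
    st <- r$start_dt
    if (!is.null(st))
      ther[[pid]] <- data.frame(primaryid = pid,
                                dsg_drug_seq = r$start_seq %||% "1",
                                start_dt = st, stringsAsFactors = FALSE)
    oc <- r$outcomes %||% character(0)
    if (length(oc))
      outc[[pid]] <- data.frame(primaryid = pid, outc_cod = oc,
                                stringsAsFactors = FALSE)
    ip <- r$indications %||% character(0)
    if (length(ip))
      indi[[pid]] <- data.frame(primaryid = pid, indi_drug_seq = "1",
                                indi_pt = ip, stringsAsFactors = FALSE)
  }
  bind <- function(x, empty) {
    if (length(x)) data.table::rbindlist(x) else empty
  }
  structure(list(
    demo = bind(demo, data.table::data.table(primaryid = character(0))),
    drug = bind(drug, data.table::data.table(primaryid = character(0),
                                             drug_seq = character(0),
                                             drugname = character(0),
                                             role_cod = character(0))),
    reac = bind(reac, data.table::data.table(primaryid = character(0),
                                             pt = character(0))),
    ther = bind(ther, data.table::data.table(primaryid = character(0),
                                             dsg_drug_seq = character(0),
                                             start_dt = character(0))),
    outc = bind(outc, data.table::data.table(primaryid = character(0),
                                             outc_cod = character(0))),
    indi = bind(indi, data.table::data.table(primaryid = character(0),
                                             indi_drug_seq = character(0),
                                             indi_pt = character(0)))),
    class = "faers_tables")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# ---- published-table cohort fixture ----------------------------------------
# A cohort whose per-subgroup marginal counts equal the printed clinical
# characteristics table: subgroup sizes 150/292/13/42; deaths 57/148/6/15;
# males 66/121/9/17 (females 42/111/3/16); lung-cancer indication
# 60/176/10/18; receipt years in 2014-2018 for 67/91/0/20; MD reporters
# 77/178/10/26.
make_published_cohort <- function() {
  sizes <- c(MONO = 150L, PLUS_CHEMO = 292L, PLUS_ICI = 13L,
             PLUS_TARGETED = 42L)
  males   <- c(66L, 121L, 9L, 17L)
  females <- c(42L, 111L, 3L, 16L)
  deaths  <- c(57L, 148L, 6L, 15L)
  lung    <- c(60L, 176L, 10L, 18L)
  yr1418  <- c(67L, 91L, 0L, 20L)
  md      <- c(77L, 178L, 10L, 26L)

  cohort <- list(); outc <- list(); indi <- list()
  pid0 <- 0L
  for (k in seq_along(sizes)) {
    n <- sizes[[k]]
    pid <- as.character(pid0 + seq_len(n)); pid0 <- pid0 + n
    sex <- c(rep("M", males[k]), rep("F", females[k]),
             rep("", n - males[k] - females[k]))
    occ <- c(rep("MD", md[k]), rep("", n - md[k]))
    fy <- c(rep(2015L, yr1418[k]), rep(2020L, n - yr1418[k]))
    cohort[[k]] <- data.table::data.table(
      primaryid = pid, caseid = pid, sex = sex, occp_cod = occ,
      reporter_country = "", fda_dt = "", event_dt = "",
      regimen = factor(names(sizes)[k],
                       levels = names(sizes)),
      is_target = TRUE, fda_year = fy)
    outc[[k]] <- data.table::data.table(primaryid = pid[seq_len(deaths[k])],
                                        outc_cod = "DE")
    indi[[k]] <- data.table::data.table(primaryid = pid[seq_len(lung[k])],
                                        indi_drug_seq = "1",
                                        indi_pt = "Non-small cell lung cancer")
  }
  list(cohort = data.table::rbindlist(cohort),
       outc = data.table::rbindlist(outc),
       indi = data.table::rbindlist(indi))
}
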
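lex <- default_lexicon()

onset_fixture <- function() {
  make_tables(list(
    list(primaryid = "1", event_dt = "20200213", drugs = "Avastin",
         pts = "Haemoptysis", start_dt = "20200101"),
    list(primaryid = "2", event_dt = "20200101", drugs = "Avastin",
         pts = "Haemoptysis", start_dt = "20200301"),
    list(primaryid = "3", event_dt = "20200501", drugs = "Avastin",
         pts = "Haemoptysis", start_dt = "202001"),
    list(primaryid = "4", event_dt = "202005", drugs = "Avastin",
         pts = "Haemoptysis", start_dt = "20200101"),
    list(primaryid = "5", event_dt = "20200303", drugs = "Avastin",
         pts = "Haemoptysis", start_dt = "20200303"),
    list(primaryid = "6", event_dt = "20200601",
         drugs = c("Avastin", "Carboplatin"), pts = "Pulmonary haemorrhage",
         start_dt = "20200401")))
}

test_that("onset derivation applies the stated exclusion order", {
  tb <- onset_fixture()
  ch <- build_cohort(tb, lexicon = lex)
  on <- compute_onset(ch$cohort, tb, lexicon = lex)
  on <- on[order(as.integer(primaryid))]
  expect_equal(on$onset_days, c(43L, NA, NA, NA, 0L, 61L))
  expect_equal(on$exclusion_reason,
               c(NA, "event_before_start", "partial_or_missing_start_date",
                 "partial_or_missing_event_date", NA, NA))
  # every target report is either used or excluded with exactly one reason
  expect_equal(sum(!is.na(on$onset_days)) +
                 sum(!is.na(on$exclusion_reason)), nrow(on))
})

test_that("earliest fully dated index start wins over partial/later ones", {
  tb <- make_tables(list(
    list(primaryid = "9", event_dt = "20200401",
         drugs = c("Avastin", "Avastin"), pts = "Haemoptysis",
         start_dt = c("202001", "20200301"), start_seq = c("1", "2"))))
  ch <- build_cohort(tb, lexicon = lex)
  on <- compute_onset(ch$cohort, tb, lexicon = lex)
  expect_equal(on$onset_days, 31L)  # the partial January row is ignored
})

test_that("onset summary uses type-7 quantiles and a proper CDF", {
  recs <- data.table::data.table(
    primaryid = as.character(1:3), regimen = "MONO",
    onset_days = c(10L, 43L, 100L), exclusion_reason = NA_character_)
  s <- summarize_onset(recs)
  expect_equal(s$median_days, 43)

  recs4 <- data.table::data.table(
    primaryid = as.character(1:4), regimen = "MONO",
    onset_days = 1:4, exclusion_reason = NA_character_)
  s4 <- summarize_onset(recs4)
  expect_equal(c(s4$q1_days, s4$median_days, s4$q3_days),
               c(1.75, 2.5, 3.25))
  expect_true(all(diff(s4$cdf$cum_frac) >= 0))
  expect_equal(s4$cdf$cum_frac[nrow(s4$cdf)], 1)
  expect_equal(sum(s4$bin_table$n), 4L)

  empty <- summarize_onset(recs4[0])
  expect_equal(empty$n_used, 0L)
  expect_true(is.na(empty$median_days))
})

test_that("onset median recovers the generative median in simulation", {
  cfg <- faers_sim_config(
    n_reports = 1200, baseline_event_prob = 0.5,
    group_specs = list(sim_group("index", c("Bevacizumab", "Avastin"),
                                 0.9, 1)),
    duplicate_rate = 0, partial_date_rate = 0,
    missing_event_date_rate = 0, onset_median_days = 40, seed = 8)
  sim <- faers_simulate(cfg)
  ch <- build_cohort(sim$tables, lexicon = lex)
  on <- compute_onset(ch$cohort, sim$tables, lexicon = lex)
  # derived onset equals the generator's ground truth day count exactly
  merged <- merge(on[!is.na(onset_days)],
                  sim$truth$reports[, .(primaryid, onset_days_true = onset_days)],
                  by = "primaryid")
  expect_gt(nrow(merged), 400)
  expect_equal(merged$onset_days, merged$onset_days_true)
  s <- summarize_onset(on)
  # sampling error of a sample median of ~500 log-normal draws
  # (sigma_log = log(4.5)) is ~3.3 days; 3 SE gives [30, 50]
  expect_gt(s$median_days, 30)
  expect_lt(s$median_days, 50)
})

test_that("cohort summary conserves counts and handles missing data", {
  fix <- make_published_cohort()
  cs <- summarize_cohort(fix$cohort, outc = fix$outc, indi = fix$indi)
  for (char in c("Gender", "Reporting year", "Reported country",
                 "Reporter", "Indication"))
    expect_equal(cs[characteristic == char & group == "Overall", sum(n)],
                 497L, info = char)

  # all-missing reports land in Unknown/Unspecified, sums preserved
  blank <- data.table::data.table(
    primaryid = c("a", "b"), caseid = c("a", "b"), sex = "",
    occp_cod = "", reporter_country = "", fda_dt = "", event_dt = "",
    regimen = factor("MONO", levels = levels(fix$cohort$regimen)),
    is_target = TRUE, fda_year = NA_integer_)
  cs2 <- summarize_cohort(blank, outc = fix$outc[0], indi = fix$indi[0])
  expect_equal(cs2[characteristic == "Gender"]$category[1], "Unknown")
  expect_true(all(cs2[group == "Overall" &
                        characteristic != "Serious outcome"]$n == 2L))
  expect_equal(cs2[characteristic == "Serious outcome" &
                     group == "Overall" & category == "Unspecified"]$n, 2L)
})
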
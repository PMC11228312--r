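test_that("config validation names the offending field", {
  expect_error(faers_sim_config(n_reports = 0), "n_reports")
  expect_error(faers_sim_config(baseline_event_prob = 0),
               "baseline_event_prob")
  expect_error(faers_sim_config(duplicate_rate = 1), "duplicate_rate")
  expect_error(faers_sim_config(onset_dispersion = 1), "onset_dispersion")
  expect_error(faers_sim_config(group_specs = list(
    sim_group("g", "X", marginal_prob = 0.1, multiplier = -1))),
    "multiplier")
  expect_error(faers_sim_config(quarters = "2020Q1"), "quarters")
})

test_that("no duplicates injected when duplicate_rate = 0", {
  sim <- faers_simulate(faers_sim_config(n_reports = 400,
                                         duplicate_rate = 0, seed = 3))
  expect_equal(length(unique(sim$tables$demo$caseid)), 400L)
  expect_equal(nrow(sim$tables$demo), 400L)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- faers_sim_config(n_reports = 250, seed = 17)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- attr(faers_generate(cfg, d1), "files")
  f2 <- attr(faers_generate(cfg, d2), "files")
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readBin(f1[i], "raw", file.size(f1[i])),
                     readBin(f2[i], "raw", file.size(f2[i])))
})

test_that("injected duplicates are exactly those the dedup rule removes", {
  cfg <- faers_sim_config(n_reports = 600, duplicate_rate = 0.25, seed = 23)
  sim <- faers_simulate(cfg)
  dd <- faers_dedup(sim$tables$demo)
  expect_equal(nrow(dd$kept), nrow(sim$truth$reports))
  expect_setequal(dd$kept$primaryid, sim$truth$reports$primaryid)
})

test_that("truth_odds_ratio reports the realized 2x2, with edge cases", {
  mk_truth <- function(g, e) structure(
    list(reports = data.table::data.table(in_g = g, event = e),
         multipliers = c(g = 1), n_duplicates = 0L),
    class = "faers_truth")
  # a=20, b=80, c=100, d=9800 -> 24.5 by hand
  t <- mk_truth(rep(c(TRUE, FALSE), c(100, 9900)),
                rep(c(TRUE, FALSE, TRUE, FALSE), c(20, 80, 100, 9800)))
  expect_equal(truth_odds_ratio(t, "g"), 24.5)
  expect_error(truth_odds_ratio(t, "nope"), "unknown group")
  # zero events anywhere: undefined
  t0 <- mk_truth(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_warning(or0 <- truth_odds_ratio(t0, "g"), "undefined")
  expect_true(is.na(or0))
})

test_that("realized odds ratio tracks the configured multiplier", {
  cfg <- faers_sim_config(
    n_reports = 40000, baseline_event_prob = 0.05,
    group_specs = list(sim_group("index", "Avastin", 0.2, 5)),
    duplicate_rate = 0, seed = 31)
  sim <- faers_simulate(cfg)
  or <- truth_odds_ratio(sim$truth, "index")
  # binomial sampling check: a ~ 1600 events, so ~3 SE is well inside 20%
  expect_gt(or, 4); expect_lt(or, 6)
})
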
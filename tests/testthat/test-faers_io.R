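test_that("partial dates parse to structured year/month/day", {
  pd <- faers_parse_date(c("20200213", "202002", "2020", "00000000", "",
                           "abc", "20200230", "20200229", "209912"))
  expect_equal(pd$year,
               c(2020L, 2020L, 2020L, NA, NA, NA, 2020L, 2020L, 2099L))
  expect_equal(pd$month, c(2L, 2L, NA, NA, NA, NA, 2L, 2L, 12L))
  # Feb 30 is calendar-invalid so the day component is dropped;
  # 2020 is a leap year so Feb 29 survives
  expect_equal(pd$day, c(13L, NA, NA, NA, NA, NA, NA, 29L, NA))
})

test_that("reader ingests a minimal quarter and counts malformed rows", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$fda_dt$event_dt$sex",
               "101$C1$20200101$20200213$F",
               "bad$row$20200101$x$y$extra$fields$here",
               "102$C2$20200301$$"),
             file.path(dir, "DEMO24q1.txt"))
  writeLines(c("primaryid$drug_seq$drugname$role_cod",
               "101$1$Avastin$PS"),
             file.path(dir, "DRUG24q1.txt"))
  writeLines(c("primaryid$pt", "101$Haemoptysis"),
             file.path(dir, "REAC24q1.txt"))

  expect_message(tb <- faers_read_quarter(dir), "1 malformed")
  expect_equal(nrow(tb$demo), 2L)
  expect_equal(attr(tb, "malformed")[["demo"]], 1L)
  # lossless accounting: valid + malformed = physical data rows
  expect_equal(nrow(tb$demo) + attr(tb, "malformed")[["demo"]], 3L)
  expect_equal(tb$demo$sex, c("F", ""))
  # short rows padded, not dropped
  expect_equal(tb$demo$event_dt, c("20200213", ""))
})

test_that("missing mandatory files and bad headers are errors", {
  dir <- withr::local_tempdir()
  writeLines(c("primaryid$caseid$fda_dt", "1$C1$20200101"),
             file.path(dir, "DEMO.txt"))
  expect_error(faers_read_quarter(dir), "DRUG")
  writeLines(c("primaryid$primaryid", "1$2"), file.path(dir, "DRUG.txt"))
  writeLines(c("primaryid$pt", "1$Nausea"), file.path(dir, "REAC.txt"))
  expect_error(faers_read_quarter(dir), "header")
})

test_that("generator output round-trips through the reader", {
  dir <- withr::local_tempdir()
  cfg <- faers_sim_config(n_reports = 300, seed = 11)
  truth <- faers_generate(cfg, dir)
  tb <- faers_read_quarter(dir)
  sim <- faers_simulate(cfg)
  for (ds in c("demo", "drug", "reac", "ther", "outc", "indi"))
    expect_equal(nrow(tb[[ds]]), nrow(sim$tables[[ds]]), info = ds)
  # re-reading yields identical tables
  tb2 <- faers_read_quarter(dir)
  expect_identical(tb$demo, tb2$demo)
  expect_identical(tb$drug, tb2$drug)
})
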
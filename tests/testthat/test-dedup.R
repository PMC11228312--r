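dd_fixture <- function(...) {
  rows <- list(...)
  data.frame(primaryid = vapply(rows, `[[`, "", 1),
             caseid = vapply(rows, `[[`, "", 2),
             fda_dt = vapply(rows, `[[`, "", 3),
             stringsAsFactors = FALSE)
}

test_that("latest FDA_DT wins; ties go to the higher PRIMARYID", {
  r <- faers_dedup(dd_fixture(c("1", "C1", "20200101"),
                              c("2", "C1", "20200301")))
  expect_equal(r$kept$primaryid, "2")
  expect_equal(r$decisions$dropped_primaryids, "1")

  r <- faers_dedup(dd_fixture(c("1", "C1", "20200101"),
                              c("9", "C1", "20200101")))
  expect_equal(r$kept$primaryid, "9")

  # numeric, not lexicographic, when all ids parse as numbers
  r <- faers_dedup(dd_fixture(c("9", "C1", "20200101"),
                              c("10", "C1", "20200101")))
  expect_equal(r$kept$primaryid, "10")

  # single record kept unchanged
  one <- dd_fixture(c("7", "C9", "20200101"))
  r <- faers_dedup(one)
  expect_equal(as.data.frame(r$kept), one)
})

test_that("undated records are kept only when their case has no dated one", {
  r <- faers_dedup(dd_fixture(c("1", "C1", "garbage"),
                              c("2", "C1", "20200101"),
                              c("3", "C2", "")))
  expect_setequal(r$kept$primaryid, c("2", "3"))
  expect_true(r$decisions[caseid == "C2"]$undated_keep)
  expect_false(r$decisions[caseid == "C1"]$undated_keep)
})

test_that("dedup is idempotent and leaves CASEIDs unique", {
  demo <- random_demo_table(50, seed = 99)
  r1 <- faers_dedup(demo)
  expect_false(anyDuplicated(r1$kept$caseid) > 0)
  r2 <- faers_dedup(r1$kept)
  expect_equal(as.data.frame(r2$kept), as.data.frame(r1$kept))
})

test_that("dedup matches the brute-force oracle on random tables", {
  for (seed in 1:60) {
    demo <- random_demo_table(sample(2:50, 1), seed = seed)
    r <- faers_dedup(demo)
    expect_equal(sort(r$kept$primaryid), oracle_dedup(demo),
                 info = paste("seed", seed))
  }
})
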
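test_that("contingency counts unique reports against the background", {
  bg <- data.table::data.table(
    primaryid = as.character(1:1000),
    is_target = c(rep(TRUE, 2), rep(FALSE, 8), rep(TRUE, 10),
                  rep(FALSE, 980)))
  ct <- build_contingency(as.character(1:10), bg)
  expect_equal(unclass(ct), list(a = 2L, b = 8L, c = 10L, d = 980L))

  # degenerate: group = background, everything flagged
  bg2 <- data.table::data.table(primaryid = c("1", "2"), is_target = TRUE)
  ct2 <- build_contingency(c("1", "2"), bg2)
  expect_equal(unclass(ct2), list(a = 2L, b = 0L, c = 0L, d = 0L))

  # empty group leaves a = b = 0
  ct3 <- build_contingency(character(0), bg)
  expect_equal(ct3$a + ct3$b, 0L)
  expect_error(build_contingency("not-there", bg), "absent")
})

test_that("ROR and CI match the closed form", {
  r <- compute_ror(list(a = 20, b = 80, c = 100, d = 9800))
  expect_equal(r$ror, 24.5)
  # frozen from the independent log-scale oracle
  expect_equal(r$ci_low, 14.4479958056, tolerance = 1e-9)
  expect_equal(r$ci_high, 41.5455546968, tolerance = 1e-9)
  expect_true(r$is_signal)

  # symmetric about 1 on the log scale when all cells equal
  r1 <- compute_ror(list(a = 10, b = 10, c = 10, d = 10))
  expect_equal(r1$ror, 1)
  expect_equal(log(r1$ci_high), -log(r1$ci_low))

  # fewer than three cases never signals, whatever the CI
  r2 <- compute_ror(list(a = 2, b = 1, c = 5, d = 5000))
  expect_gt(r2$ci_low, 1)
  expect_false(r2$is_signal)
})

test_that("zero cells are non-estimable unless Haldane is requested", {
  r <- compute_ror(list(a = 0, b = 10, c = 5, d = 100))
  expect_false(r$estimable)
  expect_true(is.na(r$ror))
  expect_false(r$is_signal)
  rh <- compute_ror(list(a = 0, b = 10, c = 5, d = 100), haldane = TRUE)
  expect_true(rh$estimable)
  expect_equal(rh$ror, (0.5 * 100.5) / (10.5 * 5.5))
})

test_that("ROR properties: transposition symmetry and monotonicity", {
  set.seed(42)
  for (i in 1:50) {
    cells <- sample(1:500, 4)
    t1 <- list(a = cells[1], b = cells[2], c = cells[3], d = cells[4])
    tT <- list(a = cells[1], b = cells[3], c = cells[2], d = cells[4])
    expect_equal(compute_ror(t1)$ror, compute_ror(tT)$ror)
    t2 <- t1; t2$a <- t1$a + 1
    expect_gt(compute_ror(t2)$ror, compute_ror(t1)$ror)
    expect_gt(compute_ror(t2)$ci_low, compute_ror(t1)$ci_low)
  }
})

test_that("subgroup chi-square matches the pooled-expectation formula", {
  tA <- list(a = 30, b = 70, c = 0, d = 0)
  tB <- list(a = 10, b = 90, c = 0, d = 0)
  cmp <- compare_groups(tA, tB)
  expect_equal(cmp$chi2, 12.5, tolerance = 1e-12)
  expect_equal(cmp$p_value, stats::pchisq(12.5, 1, lower.tail = FALSE))
  expect_false(cmp$low_expected)

  # identical proportions: no difference
  cmp0 <- compare_groups(list(a = 5, b = 15), list(a = 10, b = 30))
  expect_equal(cmp0$chi2, 0)
  expect_equal(cmp0$p_value, 1)

  # tiny counts attach the expected-cell warning
  expect_warning(compare_groups(list(a = 1, b = 30), list(a = 0, b = 40)),
                 "expected cell")
})

test_that("pair-level counting mode gives a consistent 2x2", {
  reac <- data.table::data.table(
    primaryid = c("1", "1", "2", "3", "3"),
    pt = c("Haemoptysis", "Nausea", "Rash", "Haemoptysis", "Haemoptysis"))
  ct <- build_contingency_pairs(c("1"), c("1", "2", "3"), reac)
  # report 3's duplicate PT collapses (unique pairs)
  expect_equal(unclass(ct), list(a = 1L, b = 1L, c = 1L, d = 1L))
})
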
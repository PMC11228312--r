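lex <- default_lexicon()

test_that("drug-name normalization trims, collapses and case-folds", {
  expect_equal(normalize_drugname("  AVASTIN "), "avastin")
  expect_equal(normalize_drugname("Carboplatin"), "carboplatin")
  expect_equal(normalize_drugname("nab   paclitaxel"), "nab paclitaxel")
  expect_true(normalize_drugname("BEVACIZUMAB") %in% lex$index)
  expect_equal(normalize_drugname("Taxol 100 mg", strip_dosage = TRUE),
               "taxol")
})

test_that("the packaged lexicon is normalized and disjoint", {
  expect_s3_class(lex, "drug_lexicon")
  expect_setequal(lex$index, c("bevacizumab", "avastin"))
  expect_true("erlotinib" %in% lex$targeted)
  expect_true("5-fu" %in% lex$chemotherapy)
  expect_true("amg 386" %in% lex$targeted)
  expect_length(intersect(lex$index,
                          c(lex$chemotherapy, lex$ici, lex$targeted)), 0)
})

test_that("index-report selection is exact-match with biosimilar deny-list", {
  drug <- data.table::data.table(
    primaryid = c("1", "2", "3", "4", "5"),
    drugname = c("Avastin", "bevacizumab-awwb", "Carboplatin",
                 "  BEVACIZUMAB ", "oxaliplatin"),
    role_cod = "PS")
  expect_setequal(select_index_reports(drug, lex), c("1", "4"))
  expect_error(select_index_reports(drug, structure(list(index = character(0)),
                                                    class = "drug_lexicon")),
               "empty")
})

test_that("regimen classification follows the configured precedence", {
  mk <- function(...) data.table::data.table(
    primaryid = "1", drug_seq = "1", drugname = c("Avastin", ...),
    role_cod = "PS")
  expect_equal(as.character(classify_regimens(mk(), "1", lex)), "MONO")
  expect_equal(as.character(
    classify_regimens(mk("carboplatin", "atezolizumab"), "1", lex)),
    "PLUS_CHEMO")
  expect_equal(as.character(classify_regimens(mk("erlotinib"), "1", lex)),
               "PLUS_TARGETED")
  # custom precedence flips the chemo+ici tie
  expect_equal(as.character(
    classify_regimens(mk("carboplatin", "atezolizumab"), "1", lex,
                      precedence = c("PLUS_ICI", "PLUS_CHEMO",
                                     "PLUS_TARGETED"))),
    "PLUS_ICI")
  # invariant to drug order within the report
  d1 <- mk("erlotinib", "cisplatin")
  d2 <- d1[c(3, 1, 2)]
  expect_equal(classify_regimens(d1, "1", lex),
               classify_regimens(d2, "1", lex))
})

test_that("target-event flagging is case-insensitive, set-semantic", {
  reac <- data.table::data.table(
    primaryid = c("1", "2", "3", "3"),
    pt = c("Haemoptysis", "Epistaxis", "Pulmonary haemorrhage",
           "HAEMOPTYSIS"))
  fl <- flag_target_events(reac, c("1", "2", "3"))
  expect_equal(fl, c(TRUE, FALSE, TRUE))
  expect_error(flag_target_events(reac, "1", target_pts = character(0)),
               "non-empty")
})

test_that("regimen subgroups partition the index cohort", {
  cfg <- faers_sim_config(n_reports = 1500, seed = 5)
  sim <- faers_simulate(cfg)
  dd <- faers_dedup(sim$tables$demo)
  sim$tables$demo <- dd$kept
  ch <- build_cohort(sim$tables)
  expect_equal(sum(table(ch$cohort$regimen)), nrow(ch$cohort))
  # classification agrees with the generator's ground truth
  truth <- sim$truth$reports[!is.na(regimen)]
  merged <- merge(ch$cohort[, .(primaryid, regimen)],
                  truth[, .(primaryid, truth_reg = regimen)],
                  by = "primaryid")
  expect_equal(nrow(merged), nrow(truth))
  expect_equal(as.character(merged$regimen), merged$truth_reg)
})
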
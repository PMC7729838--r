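# Synthetic cohort generator: configuration validation, reproducibility,
# marginal and conditional recovery, corruption accounting, analytic oracle.

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(cohortConfig(nPatients = 0), "nPatients")
  expect_error(cohortConfig(maleFraction = 1.2), "maleFraction")
  expect_error(cohortConfig(ageDistribution = data.frame(
    lo = c(65, 75), hi = c(74, 84), prop = c(0.6, 0.5))), "ageDistribution")
  expect_error(cohortConfig(diseaseMarginals = c(HTN = 1.5)),
               "diseaseMarginals")
  expect_error(
    cohortConfig(diseaseMarginals = c(A = 0.1, B = 0.1),
                 plantedRules = list(plantedDependency("A", "A", 0.5))),
    "target must not be in source")
  expect_error(
    cohortConfig(diseaseMarginals = c(A = 0.1, B = 0.1),
                 plantedRules = list(plantedDependency("A", "C", 0.5))),
    "unknown disease label")
  # a source decided after the rule fires is an invalid application order
  expect_error(
    cohortConfig(diseaseMarginals = c(A = 0.1, B = 0.1, C = 0.1),
                 plantedRules = list(plantedDependency("B", "C", 0.5),
                                     plantedDependency("A", "B", 0.5))),
    "reorder")
})

test_that("generation is reproducible and every record is well-formed", {
  cfg <- cohortConfig(nPatients = 200, seed = 11,
                      diseaseMarginals = c(HTN = 0.3, DM = 0.1))
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 200)
  expect_true(all(a$age >= 65))
  expect_true(all(grepl("(^|;)C34(;|$)", a$icd10_codes)))
  expect_true(all(a$gender %in% c("male", "female")))

  # byte-identical files for identical config + seed
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeEMR(generateCohort(cfg), f1, cfg)
  writeEMR(generateCohort(cfg), f2, cfg)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(paste0(f1, ".manifest.json")))
})

test_that("empirical prevalence matches configured marginals within 3 SEs", {
  cfg <- cohortConfig(nPatients = 1000, seed = 7,
                      diseaseMarginals = c(Hypertension = 0.13))
  rec <- generateCohort(cfg)
  phat <- mean(grepl("I10", rec$icd10_codes, fixed = TRUE))
  se <- sqrt(0.13 * 0.87 / 1000)
  expect_lt(abs(phat - 0.13), 3 * se)

  # a zero marginal never produces the disease
  cfg0 <- cohortConfig(
    nPatients = 500, seed = 3,
    diseaseMarginals = c(Hypertension = 0.2, `Type 2 diabetes mellitus` = 0))
  rec0 <- generateCohort(cfg0)
  expect_false(any(grepl("E11", rec0$icd10_codes, fixed = TRUE)))

  # marginal recovery across several untargeted diseases at n = 5000
  cfg2 <- cohortConfig(nPatients = 5000, seed = 21,
                       diseaseMarginals = c(A = 0.05, B = 0.15, C = 0.30))
  cat2 <- diseaseCatalog(data.frame(icd10_code = c("A01", "B01", "C01"),
                                    category = c("A", "B", "C")))
  rec2 <- generateCohort(cfg2, cat2)
  tdb <- buildTransactions(rec2, cat2)
  cnt <- itemCounts(tdb)
  for (d in names(cfg2@diseaseMarginals)) {
    p <- cfg2@diseaseMarginals[[d]]
    se <- sqrt(p * (1 - p) / 5000)
    expect_lt(abs(cnt[[d]] / 5000 - p), 3 * se)
  }
})

test_that("planted conditional dependencies are honoured", {
  cfg <- cohortConfig(nPatients = 20000, seed = 11,
                      diseaseMarginals = c(A = 0.2, B = 0.05),
                      plantedRules = list(plantedDependency("A", "B", 0.9)))
  catAB <- diseaseCatalog(data.frame(icd10_code = c("A01", "B01"),
                                     category = c("A", "B")))
  rec <- generateCohort(cfg, catAB)
  tdb <- buildTransactions(rec, catAB)
  tl <- transactionList(tdb)
  hasA <- vapply(tl, function(s) "A" %in% s, logical(1))
  hasB <- vapply(tl, function(s) "B" %in% s, logical(1))
  pBgivenA <- mean(hasB[hasA])
  se <- sqrt(0.9 * 0.1 / sum(hasA))
  expect_lt(abs(pBgivenA - 0.9), 3 * se)
})

test_that("corruption accounting is exact", {
  cfg <- cohortConfig(nPatients = 400, seed = 5,
                      diseaseMarginals = c(HTN = 0.2),
                      missingFieldRate = 0.05, duplicateKeyRate = 0.03)
  rec <- generateCohort(cfg)
  expect_equal(nrow(rec), 400 + round(0.03 * 400))
  f <- filterCohort(rec, defaultCatalog())
  rep <- f$report
  expect_equal(unname(rep["missing_field"]), round(0.05 * 400))
  expect_equal(unname(rep["duplicate_key"]), round(0.03 * 400))
  expect_equal(unname(rep["n_in"]),
               unname(rep["kept"] + rep["missing_field"] +
                      rep["no_index_code"] + rep["under_age"] +
                      rep["duplicate_key"]))
  # corrupted records blank exactly one mandatory field
  blanked <- rowSums(cbind(rec$gender == "", rec$hospital == "",
                           rec$case_number == ""))
  expect_true(all(blanked %in% c(0, 1)))
  expect_equal(sum(blanked), round(0.05 * 400))
})

test_that("toggling corruption leaves the disease pattern of base records intact", {
  base <- cohortConfig(nPatients = 300, seed = 13,
                       diseaseMarginals = c(HTN = 0.25, DM = 0.1))
  dirty <- cohortConfig(nPatients = 300, seed = 13,
                        diseaseMarginals = c(HTN = 0.25, DM = 0.1),
                        missingFieldRate = 0.1, duplicateKeyRate = 0.1)
  a <- generateCohort(base)
  b <- generateCohort(dirty)
  expect_identical(a$icd10_codes, b$icd10_codes[seq_len(300)])
})

test_that("expectedRuleMetrics matches closed forms and enumeration", {
  # independence: lift is exactly 1
  cfg <- cohortConfig(diseaseMarginals = c(A = 0.2, B = 0.5))
  m <- expectedRuleMetrics(cfg, "A", "B")
  expect_equal(unname(m["lift"]), 1)
  expect_equal(unname(m["support"]), 0.1)

  # forced co-occurrence: confidence 1
  cfg1 <- cohortConfig(diseaseMarginals = c(A = 0.2, B = 0.05),
                       plantedRules = list(plantedDependency("A", "B", 1.0)))
  expect_equal(unname(expectedRuleMetrics(cfg1, "A", "B")["confidence"]), 1)

  # 4-cell joint law: A = 0.2, B marginal 0.05, P(B|A) = 0.9
  cfg2 <- cohortConfig(diseaseMarginals = c(A = 0.2, B = 0.05),
                       plantedRules = list(plantedDependency("A", "B", 0.9)))
  m2 <- expectedRuleMetrics(cfg2, "A", "B")
  pB <- 0.2 * 0.9 + 0.8 * 0.05
  expect_equal(unname(m2["support"]), 0.18)
  expect_equal(unname(m2["confidence"]), 0.9)
  expect_equal(unname(m2["lift"]), 0.9 / pB)

  expect_error(expectedRuleMetrics(cfg, "A", "Z"), "unknown disease")
})

test_that("cohort configs round-trip through YAML and JSON", {
  cfg <- cohortConfig(nPatients = 120, seed = 9,
                      diseaseMarginals = c(A = 0.1, B = 0.2),
                      plantedRules = list(plantedDependency("A", "B", 0.8)),
                      missingFieldRate = 0.02)
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    n_patients = 120, seed = 9,
    disease_marginals = list(A = 0.1, B = 0.2),
    planted_rules = list(list(source = "A", target = "B", prob = 0.8)),
    missing_field_rate = 0.02), yml)
  cfg2 <- readCohortConfig(yml)
  expect_identical(generateCohort(cfg, miniCatalog()),
                   generateCohort(cfg2, miniCatalog()))
})
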
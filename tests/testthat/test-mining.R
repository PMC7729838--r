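# Apriori mining, rule generation, brute-force oracle, dedup, summaries.

test_that("rule metrics are exact count ratios", {
  # 4 transactions enumerated by hand:
  # {A,B}, {A,B}, {A}, {B} -> support 2/4, confidence 2/3, lift 8/9
  tdb <- tdbOf(c("A", "B"), c("A", "B"), "A", "B")
  m <- ruleMetrics(tdb, "A", "B")
  expect_equal(unname(m["support"]), 0.5)
  expect_equal(unname(m["confidence"]), 2 / 3)
  expect_equal(unname(m["lift"]), 8 / 9)

  # P(Y) = 1 limit: lift equals confidence
  tdb2 <- tdbOf(c("A", "Y"), "Y", "Y")
  m2 <- ruleMetrics(tdb2, "A", "Y")
  expect_equal(unname(m2["lift"]), unname(m2["confidence"]))

  expect_error(ruleMetrics(tdb, character(0), "B"), "non-empty")
  expect_error(ruleMetrics(tdb, "A", "A"), "must not appear")
  tdb3 <- tdbOf("A", items = c("A", "B", "C"))
  expect_error(ruleMetrics(tdb3, "B", "A"), "confidence undefined")
  expect_error(ruleMetrics(tdb3, "A", "B"), "lift undefined")
})

test_that("independently planted diseases show lift near 1", {
  cfg <- cohortConfig(nPatients = 20000, seed = 31,
                      diseaseMarginals = c(X = 0.2, Y = 0.5))
  cat2 <- diseaseCatalog(data.frame(icd10_code = c("X01", "Y01"),
                                    category = c("X", "Y")))
  tdb <- buildTransactions(generateCohort(cfg, cat2), cat2)
  m <- ruleMetrics(tdb, "X", "Y")
  # delta-method SE of the lift estimate under independence
  se <- sqrt((1 - 0.2) / (0.2 * 20000) + (1 - 0.5) / (0.5 * 20000) +
             (1 - 0.1) / (0.1 * 20000))
  expect_lt(abs(m["lift"] - 1), 3 * se)
})

test_that("apriori returns exactly the itemsets above the strict support bound", {
  tdb <- toyTdb()
  its <- aprioriFrequentItemsets(tdb, minSupport = 0.3, maxSize = 3)
  # exhaustive enumeration of all 7 non-empty subsets of {A,B,C} by hand:
  # A 4/6, B 4/6, C 3/6, AB 2/6, AC 2/6, BC 2/6, ABC 1/6; strict > 0.3
  # keeps everything except ABC (1/6)
  expect_equal(unname(vapply(its$items, paste, character(1), collapse = "")),
               c("A", "B", "C", "AB", "AC", "BC"))
  expect_equal(its$support, c(4, 4, 3, 2, 2, 2) / 6)

  # min support above every frequency: nothing survives
  expect_equal(nrow(aprioriFrequentItemsets(tdb, minSupport = 0.9)), 0L)

  # support is anti-monotone along subset inclusion
  its2 <- aprioriFrequentItemsets(tdb, minSupport = 0, maxSize = 3)
  key <- vapply(its2$items, paste, character(1), collapse = "\r")
  supp <- stats::setNames(its2$support, key)
  for (i in which(its2$size > 1)) {
    s <- its2$items[[i]]
    for (drop in seq_along(s)) {
      sub <- paste(s[-drop], collapse = "\r")
      expect_lte(its2$support[i], supp[[sub]] + 1e-15)
    }
  }
})

test_that("apriori + rule generation matches the brute-force oracle", {
  # fixed toy case with thresholds (0.1, 0.5, 1.0)
  tdb <- toyTdb()
  a <- mineRules(tdb, minSupport = 0.1, minConfidence = 0.5, minLift = 1.0)
  b <- bruteForceRules(tdb, minSupport = 0.1, minConfidence = 0.5,
                       minLift = 1.0)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # randomized equivalence over small transaction sets and random thresholds
  set.seed(99)
  for (rep in 1:40) {
    tdb <- randomTdb(sample(2:8, 1), sample(5:40, 1))
    ms <- stats::runif(1, 0, 0.3)
    mc <- stats::runif(1, 0, 0.9)
    ml <- stats::runif(1, 0, 2)
    a <- mineRules(tdb, ms, mc, ml, maxSize = 3)
    b <- bruteForceRules(tdb, ms, mc, ml, maxSize = 3)
    expect_identical(as.data.frame(a), as.data.frame(b))
  }
})

test_that("metric identities hold on every emitted rule", {
  set.seed(5)
  tdb <- randomTdb(10, 60)
  rules <- mineRules(tdb, minSupport = 0.01, minConfidence = 0.1,
                     minLift = 0.1)
  q <- ruleQuality(rules)
  expect_gt(nrow(q), 0)
  pY <- q$rhsCount / q$n
  pX <- q$lhsCount / q$n
  expect_true(all(abs(q$lift * pY - q$confidence) < 1e-12))
  expect_true(all(abs(q$confidence * pX - q$support) < 1e-12))
  expect_true(all(q$support <= q$confidence + 1e-15))
  expect_true(all(q$support <= pX + 1e-15 & q$support <= pY + 1e-15))
})

test_that("raising any threshold yields a subset of the rules", {
  set.seed(17)
  tdb <- randomTdb(8, 50)
  base <- as.data.frame(mineRules(tdb, 0.02, 0.3, 0.8))
  idOf <- function(df) paste(df$lhs, df$rhs)
  for (args in list(c(0.1, 0.3, 0.8), c(0.02, 0.6, 0.8), c(0.02, 0.3, 1.5))) {
    sub <- as.data.frame(mineRules(tdb, args[1], args[2], args[3]))
    expect_true(all(idOf(sub) %in% idOf(base)))
  }
})

test_that("perfectly correlated pair yields symmetric rules with lift 1/prevalence", {
  # A == B in 3 of 10 transactions
  sets <- c(replicate(3, c("A", "B"), simplify = FALSE),
            replicate(7, character(0), simplify = FALSE))
  tdb <- TransactionDB(sets, items = c("A", "B"))
  rules <- mineRules(tdb, minSupport = 0.01, minConfidence = 0.5,
                     minLift = 2, maxSize = 2)
  df <- as.data.frame(rules)
  expect_equal(nrow(df), 2)
  expect_equal(df$confidence, c(1, 1))
  expect_equal(df$lift, c(1 / 0.3, 1 / 0.3))
})

test_that("brute force degenerate cases", {
  expect_equal(length(bruteForceRules(tdbOf("A", items = c("A")))), 0L)
  expect_equal(length(bruteForceRules(
    TransactionDB(list(), items = c("A", "B")))), 0L)
  wide <- TransactionDB(list(paste0("I", 1:21)), items = paste0("I", 1:21))
  expect_error(bruteForceRules(wide), "guard")
})

test_that("same-itemset dedup keeps the highest-confidence direction", {
  ref <- referenceRules()
  dd <- dedupeByItemset(ref)
  expect_equal(length(dd), 30L)
  expect_equal(dd@info$dedup$nGroups, 30L)
  expect_equal(dd@info$dedup$nDropped, 11L)
  # the itemset shared by published rules #9 and #10 keeps #9 (conf 0.92)
  kept <- as.data.frame(dd)
  i9 <- kept$lhs == "Atherosclerotic heart disease|Ischemic cardiomyopathy" &
    kept$rhs == "Heart failure"
  expect_true(any(i9))
  expect_equal(kept$confidence[i9], 0.92)

  # all-distinct itemsets pass through unchanged (a second dedup is a no-op)
  again <- dedupeByItemset(dd)
  expect_identical(as.data.frame(again), as.data.frame(dd))
})

test_that("rule summaries reproduce the published metric ranges", {
  s <- summarizeRules(referenceRules())
  expect_equal(round(s$mean[s$metric == "lift"], 2), 4.91)
  expect_equal(s$max[s$metric == "lift"], 8.58)
  expect_equal(s$min[s$metric == "confidence"], 0.50)
  expect_equal(s$max[s$metric == "confidence"], 0.92)
  expect_equal(s$min[s$metric == "support"], 0.01)
  expect_equal(s$max[s$metric == "support"], 0.06)

  one <- mineRules(tdbOf(c("A", "B"), c("A", "B"), "C"), 0.1, 0.5, 1.01,
                   maxSize = 2)
  s1 <- summarizeRules(one)
  expect_equal(s1$min, s1$max)
  expect_equal(s1$min, s1$mean)

  empty <- summarizeRules(dedupeByItemset(
    mineRules(toyTdb(), 0.99, 0.99, 99)))
  expect_equal(nrow(empty), 0L)
})
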
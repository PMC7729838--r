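# Co-occurrence network construction, modularity, community detection.

test_that("network counts nodes and edges by direct co-occurrence", {
  tdb <- tdbOf(c("A", "B"), c("A", "B"), c("A", "C"))
  nw <- buildNetwork(tdb)
  g <- nw@graph
  cnt <- stats::setNames(igraph::V(g)$count, igraph::V(g)$name)
  expect_equal(cnt[["A"]], 3)
  expect_equal(cnt[["B"]], 2)
  expect_equal(cnt[["C"]], 1)
  ed <- edgeList(nw)
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  expect_setequal(key, c("A B", "A C"))
  expect_equal(ed$weight[key == "A B"], 2)
  expect_equal(ed$weight[key == "A C"], 1)
  # edge weight cannot exceed either endpoint count
  expect_true(all(ed$weight <= pmin(cnt[ed$from], cnt[ed$to])))

  # raising the co-occurrence threshold prunes edges
  nw2 <- buildNetwork(tdb, minCooccurrence = 2)
  expect_equal(nrow(edgeList(nw2)), 1L)
  expect_error(buildNetwork(tdb, nodeSet = character(0)), "non-empty")
})

test_that("network is symmetric and invariant under transaction permutation", {
  set.seed(3)
  tl <- lapply(1:40, function(i) sort(sample(LETTERS[1:6], sample(0:4, 1))))
  nw1 <- buildNetwork(TransactionDB(tl, items = LETTERS[1:6]))
  nw2 <- buildNetwork(TransactionDB(tl[sample(40)], items = LETTERS[1:6]))
  e1 <- edgeList(nw1); e2 <- edgeList(nw2)
  norm <- function(e) e[order(pmin(e$from, e$to), pmax(e$from, e$to)),
                        c("weight")]
  expect_equal(norm(e1), norm(e2))
})

test_that("edge weights of independent diseases match binomial expectation", {
  cfg <- cohortConfig(nPatients = 20000, seed = 19,
                      diseaseMarginals = c(A = 0.10, B = 0.15, C = 0.08))
  cat3 <- diseaseCatalog(data.frame(icd10_code = c("A01", "B01", "C01"),
                                    category = c("A", "B", "C")))
  tdb <- buildTransactions(generateCohort(cfg, cat3), cat3)
  ed <- edgeList(buildNetwork(tdb))
  marg <- cfg@diseaseMarginals
  for (i in seq_len(nrow(ed))) {
    p <- marg[[ed$from[i]]] * marg[[ed$to[i]]]
    se <- sqrt(20000 * p * (1 - p))
    expect_lt(abs(ed$weight[i] - 20000 * p), 3 * se)
  }
})

test_that("modularity matches direct evaluation of the weighted formula", {
  # two disconnected equal-weight edges, each its own community: Q = 0.5
  g <- graphOf(data.frame(from = c("a", "c"), to = c("b", "d"), weight = 1))
  q <- modularityQ(g, c(a = 1, b = 1, c = 2, d = 2))
  expect_equal(q, 0.5, tolerance = 1e-12)

  # everything in one community: Q = 0 by the degree-sum identity
  expect_equal(modularityQ(g, c(a = 1, b = 1, c = 1, d = 1)), 0,
               tolerance = 1e-12)

  # agrees with igraph's implementation on a random weighted graph
  set.seed(8)
  g2 <- igraph::sample_gnp(10, 0.5)
  igraph::V(g2)$name <- letters[1:10]
  igraph::E(g2)$weight <- sample(1:5, igraph::gsize(g2), replace = TRUE)
  memb <- sample(1:3, 10, replace = TRUE)
  expect_equal(
    modularityQ(g2, stats::setNames(memb, letters[1:10])),
    igraph::modularity(g2, memb, weights = igraph::E(g2)$weight),
    tolerance = 1e-12)

  expect_error(modularityQ(g, c(a = 1, b = 1, c = 2)), "missing node")
})

test_that("community detection separates two cliques joined by a weak edge", {
  ed <- rbind(
    expand.grid(from = c("a", "b", "c"), to = c("a", "b", "c")),
    expand.grid(from = c("x", "y", "z"), to = c("x", "y", "z")))
  ed <- ed[as.character(ed$from) < as.character(ed$to), ]
  ed$weight <- 10
  ed <- rbind(ed, data.frame(from = "c", to = "x", weight = 1))
  g <- graphOf(ed)
  part <- detectCommunities(g, seed = 1)
  a <- communityAssignment(part)
  expect_equal(length(unique(a)), 2L)
  expect_equal(length(unique(a[c("a", "b", "c")])), 1L)
  expect_equal(length(unique(a[c("x", "y", "z")])), 1L)
  # matches exhaustive maximisation on this 6-node instance
  best <- exhaustiveBestPartition(g)
  expect_equal(part@q, best$q, tolerance = 1e-9)
  # reported q is recomputable from the assignment
  expect_equal(part@q, modularityQ(g, a), tolerance = 1e-12)
  # deterministic under a fixed seed
  expect_identical(communityAssignment(detectCommunities(g, seed = 1)), a)
})

test_that("single-edge graph picks whichever partition the formula prefers", {
  g <- graphOf(data.frame(from = "a", to = "b", weight = 1))
  # both candidate partitions enumerated directly
  qTogether <- modularityQ(g, c(a = 1, b = 1))
  qApart <- modularityQ(g, c(a = 1, b = 2))
  part <- detectCommunities(g, seed = 4)
  expect_equal(part@q, max(qTogether, qApart), tolerance = 1e-12)
})

test_that("exhaustive search certifies near-optimality on small graphs", {
  set.seed(12)
  okCount <- 0L
  for (rep in 1:20) {
    n <- sample(4:7, 1)
    g <- igraph::sample_gnp(n, 0.5)
    igraph::V(g)$name <- letters[seq_len(n)]
    if (igraph::gsize(g) == 0) next
    igraph::E(g)$weight <- sample(1:10, igraph::gsize(g), replace = TRUE)
    det <- detectCommunities(g, seed = rep)
    best <- exhaustiveBestPartition(g)
    expect_lte(det@q, best$q + 1e-9)
    if (abs(det@q - best$q) < 1e-9) okCount <- okCount + 1L
  }
  expect_gte(okCount, 18L)
})

test_that("ICD-chapter partition and graph exports carry attributes", {
  tdb <- buildTransactions(
    generateCohort(cohortConfig(nPatients = 400, seed = 23)),
    defaultCatalog())
  nw <- buildNetwork(tdb)
  chap <- icdChapterPartition(nw)
  expect_equal(chap@q, modularityQ(nw, chap@assignment), tolerance = 1e-12)

  part <- detectCommunities(nw, seed = 2)
  gml <- tempfile(fileext = ".graphml")
  gexf <- tempfile(fileext = ".gexf")
  writeGraphML(nw, gml, part)
  writeGEXF(nw, gexf, part)
  x <- xml2::read_xml(gml)   # well-formed XML with our attributes
  expect_true(grepl("graphml", xml2::xml_name(x)))
  y <- xml2::read_xml(gexf)
  expect_equal(xml2::xml_name(y), "gexf")
  nodes <- xml2::xml_find_all(y, ".//*[local-name()='node']")
  expect_equal(length(nodes), igraph::gorder(nw@graph))
})
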
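#' @importClassesFrom Matrix ngCMatrix
NULL

#' DiseaseCatalog: ICD-10 code to morbidity-category mapping
#'
#' Maps ICD-10 diagnosis codes to the morbidity categories over which
#' transactions are built, and declares which codes identify the index
#' disease (lung cancer, C34). Every code maps to exactly one category and
#' index codes are disjoint from the comorbidity categories.
#'
#' @slot entries data.frame with columns `icd10_code`, `category` and
#'   `chapter` (ICD-10 chapter tag used for node grouping in network plots).
#' @slot indexCodes character vector of ICD-10 codes identifying the index
#'   disease; a record must carry at least one of these to enter the cohort.
#' @seealso [defaultCatalog()], [readCatalog()]
#' @export
setClass("DiseaseCatalog",
  representation(entries = "data.frame", indexCodes = "character"),
  validity = function(object) {
    e <- object@entries
    msg <- character()
    if (!all(c("icd10_code", "category") %in% names(e)))
      msg <- c(msg, "entries must have columns 'icd10_code' and 'category'")
    else {
      if (anyDuplicated(e$icd10_code))
        msg <- c(msg, "each ICD-10 code must map to exactly one category")
      if (any(object@indexCodes %in% e$icd10_code))
        msg <- c(msg, "index codes must be disjoint from comorbidity categories")
    }
    if (length(object@indexCodes) < 1L)
      msg <- c(msg, "at least one index code is required")
    if (length(msg)) msg else TRUE
  }
)

#' TransactionDB: per-patient comorbidity sets
#'
#' The transaction database over which itemset support is counted: one
#' transaction per eligible patient, holding the set of morbidity-category
#' labels recorded for that patient (the index disease is excluded).
#' Patients with zero comorbidities are retained as empty transactions and
#' count in the support denominator.
#'
#' Internally a sparse logical incidence matrix (items in rows, patients in
#' columns), in the style of the itemMatrix representation used by
#' market-basket mining packages.
#'
#' @slot incidence ngCMatrix, items x patients; dimnames give item labels
#'   and patient keys.
#' @slot info list of bookkeeping fields (e.g. `unknownCodes`, the tally of
#'   diagnosis codes dropped because they are absent from the catalog).
#' @seealso [TransactionDB()], [buildTransactions()]
#' @export
setClass("TransactionDB",
  representation(incidence = "ngCMatrix", info = "list"),
  validity = function(object) {
    msg <- character()
    keys <- colnames(object@incidence)
    # Matrix stores character(0) dimnames as NULL, so an empty database
    # legitimately has NULL column names
    if ((is.null(keys) && ncol(object@incidence) > 0L) || anyDuplicated(keys))
      msg <- c(msg, "patient keys (column names) must be present and unique")
    if (is.null(rownames(object@incidence)))
      msg <- c(msg, "item labels (row names) must be present")
    if (length(msg)) msg else TRUE
  }
)

#' AssociationRuleSet: mined comorbidity rules
#'
#' A set of association rules X => Y with a non-empty left-hand side X, a
#' single right-hand-side item Y, and quality metrics: support P(X,Y),
#' confidence P(Y|X) and lift P(X,Y) / (P(X) P(Y)). Metrics are kept at full
#' precision; printing rounds to two decimals.
#'
#' @slot lhs list of character vectors (sorted item labels), one per rule.
#' @slot rhs character vector, one item per rule.
#' @slot quality data.frame with columns `support`, `confidence`, `lift`,
#'   and, for rules mined from data, the underlying `count`, `lhsCount`,
#'   `rhsCount` and `n`.
#' @slot info list recording provenance (thresholds, n, dedup report, ...).
#' @seealso [mineRules()], [dedupeByItemset()]
#' @export
setClass("AssociationRuleSet",
  representation(lhs = "list", rhs = "character", quality = "data.frame",
                 info = "list"),
  validity = function(object) {
    msg <- character()
    nr <- length(object@rhs)
    if (length(object@lhs) != nr || nrow(object@quality) != nr)
      msg <- c(msg, "lhs, rhs and quality must describe the same number of rules")
    if (nr > 0) {
      if (any(lengths(object@lhs) < 1L))
        msg <- c(msg, "every rule needs a non-empty lhs")
      if (any(mapply(function(x, y) y %in% x, object@lhs, object@rhs)))
        msg <- c(msg, "rhs item must not appear in its lhs")
      q <- object@quality
      if (all(c("support", "confidence") %in% names(q)) &&
          any(q$support > q$confidence + 1e-12))
        msg <- c(msg, "support must not exceed confidence")
    }
    if (length(msg)) msg else TRUE
  }
)

#' ParetoResult: rank-frequency analysis with an 80% head
#'
#' Diseases ordered by patient count with cumulative coverage, and the
#' Pareto head: the shortest prefix whose cumulative proportion reaches the
#' threshold (default 0.80). Achieved coverage may exceed the threshold.
#'
#' @slot ranked data.frame with columns `rank`, `category`, `count`,
#'   `cumulative`.
#' @slot threshold numeric in (0, 1].
#' @slot headSize integer, number of diseases in the head.
#' @slot coverage numeric, cumulative proportion achieved by the head.
#' @slot denominator "disease_instances" or "patients_with_comorbidity".
#' @seealso [rankDiseases()], [paretoHead()]
#' @export
setClass("ParetoResult",
  representation(ranked = "data.frame", threshold = "numeric",
                 headSize = "integer", coverage = "numeric",
                 denominator = "character"),
  validity = function(object) {
    msg <- character()
    r <- object@ranked
    if (nrow(r)) {
      if (is.unsorted(rev(r$count))) msg <- c(msg, "counts must be non-increasing")
      if (is.unsorted(r$cumulative)) msg <- c(msg, "cumulative must be non-decreasing")
    }
    if (object@threshold <= 0 || object@threshold > 1)
      msg <- c(msg, "threshold must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' ComorbidityNetwork: weighted disease co-occurrence graph
#'
#' An undirected graph over morbidity categories. A node's weight is the
#' number of patients carrying the disease; an edge's weight is the number
#' of patients carrying both endpoints. Pairs co-occurring in fewer than
#' `minCooccurrence` patients are omitted; there are no self-loops.
#'
#' @slot graph an igraph object with vertex attributes `count` and
#'   `chapter`, and edge attribute `weight`.
#' @slot nPatients integer, the number of transactions behind the counts.
#' @slot minCooccurrence integer, the edge-inclusion threshold used.
#' @seealso [buildNetwork()], [detectCommunities()]
#' @export
setClass("ComorbidityNetwork",
  representation(graph = "ANY", nPatients = "integer",
                 minCooccurrence = "integer")
)

#' CommunityPartition: modularity communities of a comorbidity network
#'
#' @slot assignment named integer vector mapping each node label to a
#'   community id (1-based, consecutive).
#' @slot q numeric, the weighted Newman-Girvan modularity of the partition,
#'   recomputable from the network with [modularityQ()].
#' @slot resolution numeric resolution parameter used (1 = classic).
#' @seealso [detectCommunities()], [modularityQ()]
#' @export
setClass("CommunityPartition",
  representation(assignment = "integer", q = "numeric",
                 resolution = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@assignment) && is.null(names(object@assignment)))
      msg <- c(msg, "assignment must be named by node label")
    if (object@q < -0.5 - 1e-9 || object@q > 1 + 1e-9)
      msg <- c(msg, "modularity must lie in [-0.5, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' CohortConfig: parameters of the synthetic EMR cohort generator
#'
#' Defines the statistical structure of a simulated cohort of older
#' lung-cancer patients: demographics, per-disease marginal prevalences,
#' planted conditional dependencies (which make rule metrics analytically
#' computable), and injectable data-quality defects.
#'
#' @slot nPatients positive integer, number of base records.
#' @slot ageDistribution data.frame with columns `lo`, `hi`, `prop`; ages
#'   are drawn uniformly within the sampled band. Proportions sum to 1.
#' @slot maleFraction numeric in \[0, 1\].
#' @slot diseaseMarginals named numeric vector of marginal prevalences in
#'   \[0, 1\], one per comorbidity category.
#' @slot plantedRules list of planted dependencies (see
#'   [plantedDependency()]), applied in list order; a later applicable
#'   dependency overrides an earlier one for the same target.
#' @slot missingFieldRate numeric in \[0, 1\]: proportion of records with one
#'   randomly blanked mandatory field (gender, hospital or case number).
#' @slot duplicateKeyRate numeric in \[0, 1\]: proportion of records
#'   re-emitted with an identical primary key.
#' @slot seed integer RNG seed.
#' @seealso [cohortConfig()], [generateCohort()], [expectedRuleMetrics()]
#' @export
setClass("CohortConfig",
  representation(nPatients = "integer", ageDistribution = "data.frame",
                 maleFraction = "numeric", diseaseMarginals = "numeric",
                 plantedRules = "list", missingFieldRate = "numeric",
                 duplicateKeyRate = "numeric", seed = "integer"),
  validity = function(object) .validCohortConfig(object)
)

# Validity logic shared with the constructor so errors name the offending
# field before an invalid object ever exists.
.validCohortConfig <- function(object) {
  msg <- character()
  if (length(object@nPatients) != 1L || is.na(object@nPatients) ||
      object@nPatients < 1L)
    msg <- c(msg, "nPatients: must be a positive integer")
  ad <- object@ageDistribution
  if (!all(c("lo", "hi", "prop") %in% names(ad)))
    msg <- c(msg, "ageDistribution: needs columns lo, hi, prop")
  else {
    if (any(ad$prop < 0 | ad$prop > 1) ||
        abs(sum(ad$prop) - 1) > 1e-9)
      msg <- c(msg, "ageDistribution: proportions must lie in [0,1] and sum to 1")
    if (any(ad$hi < ad$lo)) msg <- c(msg, "ageDistribution: hi < lo")
  }
  if (object@maleFraction < 0 || object@maleFraction > 1)
    msg <- c(msg, "maleFraction: must lie in [0,1]")
  dm <- object@diseaseMarginals
  if (length(dm)) {
    if (is.null(names(dm)) || any(!nzchar(names(dm))))
      msg <- c(msg, "diseaseMarginals: must be named by category")
    if (any(dm < 0 | dm > 1))
      msg <- c(msg, "diseaseMarginals: prevalences must lie in [0,1]")
    if (anyDuplicated(names(dm)))
      msg <- c(msg, "diseaseMarginals: duplicated category names")
  }
  for (i in seq_along(object@plantedRules)) {
    r <- object@plantedRules[[i]]
    lab <- paste0("plantedRules[", i, "]")
    if (!is.list(r) || !all(c("source", "target", "prob") %in% names(r))) {
      msg <- c(msg, paste0(lab, ": needs fields source, target, prob"))
      next
    }
    if (length(r$source) < 1L || length(r$source) > 2L)
      msg <- c(msg, paste0(lab, ": source must hold 1 or 2 labels"))
    if (r$target %in% r$source)
      msg <- c(msg, paste0(lab, ": target must not be in source"))
    if (r$prob < 0 || r$prob > 1)
      msg <- c(msg, paste0(lab, ": prob must lie in [0,1]"))
    known <- names(dm)
    bad <- setdiff(c(r$source, r$target), known)
    if (length(bad))
      msg <- c(msg, paste0(lab, ": unknown disease label(s) ",
                           paste(bad, collapse = ", ")))
    # a source must have its final state before this rule fires: it may not
    # be the target of this or any later rule (acyclic application order)
    later <- object@plantedRules[seq(i, length(object@plantedRules))]
    laterTargets <- vapply(later, function(x) as.character(x$target)[1],
                           character(1))
    if (any(r$source %in% laterTargets))
      msg <- c(msg, paste0(lab, ": source is the target of this or a ",
                           "later dependency; reorder the rules"))
  }
  if (object@missingFieldRate < 0 || object@missingFieldRate > 1)
    msg <- c(msg, "missingFieldRate: must lie in [0,1]")
  if (object@duplicateKeyRate < 0 || object@duplicateKeyRate > 1)
    msg <- c(msg, "duplicateKeyRate: must lie in [0,1]")
  if (length(msg)) msg else TRUE
}
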
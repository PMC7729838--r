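#' Support, confidence and lift of a single rule
#'
#' Exact counting semantics: each metric is a ratio of transaction counts,
#' divided once, with no intermediate rounding. support = |lhs u rhs
#' contained| / n, confidence = support / P(lhs), lift = support /
#' (P(lhs) P(rhs)).
#'
#' @param tdb a [TransactionDB-class] with at least one transaction.
#' @param lhs non-empty character vector of item labels.
#' @param rhs single item label, not in `lhs`.
#' @return named numeric vector `c(support, confidence, lift)` with
#'   attribute `counts` holding the underlying integer counts.
#' @export
ruleMetrics <- function(tdb, lhs, rhs) {
  n <- nPatients(tdb)
  if (n == 0L) stop("transaction database is empty")
  if (!length(lhs)) stop("lhs must be non-empty")
  if (rhs %in% lhs) stop("rhs must not appear in lhs")
  items <- itemLabels(tdb)
  if (length(bad <- setdiff(c(lhs, rhs), items)))
    stop("unknown item(s): ", paste(bad, collapse = ", "))
  m <- tdb@incidence
  holds <- function(set) {
    sub <- m[set, , drop = FALSE]
    Matrix::colSums(sub) == length(set)
  }
  cLhs <- sum(holds(lhs))
  cRhs <- sum(holds(rhs))
  cBoth <- sum(holds(c(lhs, rhs)))
  if (cLhs == 0L) stop("P(lhs) = 0: confidence undefined, rule not emitted")
  if (cRhs == 0L) stop("P(rhs) = 0: lift undefined, rule not emitted")
  out <- c(support = cBoth / n,
           confidence = cBoth / cLhs,
           lift = (cBoth * n) / (cLhs * cRhs))
  attr(out, "counts") <- c(both = cBoth, lhs = cLhs, rhs = cRhs, n = n)
  out
}

#' Apriori frequent-itemset mining
#'
#' Classic level-wise search: level-k candidates are generated by joining
#' frequent (k-1)-itemsets sharing their first k-2 items and pruned by
#' downward closure (every (k-1)-subset of a candidate must itself be
#' frequent) before their supports are counted. The support filter is
#' strict (`support > minSupport`), matching the convention used for the
#' published thresholds.
#'
#' @param tdb a [TransactionDB-class].
#' @param minSupport strict lower bound on support (default 0.01).
#' @param maxSize largest itemset size searched (default 3).
#' @return data.frame with columns `items` (list of sorted label vectors),
#'   `size`, `count`, `support`, ordered by (size, lexicographic items).
#' @export
aprioriFrequentItemsets <- function(tdb, minSupport = 0.01, maxSize = 3L) {
  stopifnot(minSupport >= 0, maxSize >= 2L)
  n <- nPatients(tdb)
  if (n == 0L)
    return(data.frame(items = I(list()), size = integer(0),
                      count = integer(0), support = numeric(0)))
  X <- as.matrix(Matrix::t(tdb@incidence))   # patients x items, logical
  items <- colnames(X)
  minCount <- minSupport * n                 # strict: count > minCount

  counts1 <- colSums(X)
  freq <- list()
  lev <- lapply(which(counts1 > minCount), function(i) i)
  levCount <- counts1[counts1 > minCount]
  if (length(lev))
    freq[[1L]] <- list(sets = lev, counts = as.integer(levCount))
  k <- 1L
  while (k < maxSize && length(freq) == k && length(freq[[k]]$sets) > 1L) {
    prev <- freq[[k]]$sets
    prevKey <- vapply(prev, paste, character(1), collapse = ".")
    # join step: pairs sharing the first k-1 indices
    pref <- vapply(prev, function(s)
      paste(s[seq_len(k - 1L)], collapse = "."), character(1))
    cand <- list()
    for (grp in split(seq_along(prev), pref)) {
      if (length(grp) < 2L) next
      cb <- utils::combn(grp, 2L)
      for (c2 in seq_len(ncol(cb))) {
        a <- prev[[cb[1L, c2]]]; b <- prev[[cb[2L, c2]]]
        cand[[length(cand) + 1L]] <- sort(unique(c(a, b)))
      }
    }
    if (!length(cand)) break
    # prune step: all k-subsets must be frequent
    keep <- vapply(cand, function(s) {
      subs <- utils::combn(s, k)
      all(apply(subs, 2L, paste, collapse = ".") %in% prevKey)
    }, logical(1))
    cand <- cand[keep]
    if (!length(cand)) break
    cnt <- vapply(cand, function(s)
      sum(rowSums(X[, s, drop = FALSE]) == length(s)), numeric(1))
    ok <- cnt > minCount
    if (!any(ok)) break
    freq[[k + 1L]] <- list(sets = cand[ok], counts = as.integer(cnt[ok]))
    k <- k + 1L
  }

  sets <- unlist(lapply(freq, `[[`, "sets"), recursive = FALSE)
  cnts <- unlist(lapply(freq, `[[`, "counts"))
  if (is.null(sets)) sets <- list()
  labsets <- lapply(sets, function(s) items[s])
  out <- data.frame(size = lengths(labsets), count = as.integer(cnts %||% integer(0)),
                    support = (cnts %||% integer(0)) / n)
  out$items <- I(labsets)
  key <- vapply(labsets, paste, character(1), collapse = "\r")
  out <- out[order(out$size, key), c("items", "size", "count", "support")]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

itemsetKey <- function(items) {
  vapply(items, function(s) paste(sort(s), collapse = "\r"), character(1))
}

newRuleSet <- function(lhs, rhs, quality, info = list()) {
  methods::new("AssociationRuleSet", lhs = lhs, rhs = rhs,
               quality = quality, info = info)
}

sortRules <- function(rs) {
  if (!length(rs@rhs)) return(rs)
  size <- lengths(rs@lhs) + 1L
  lhsKey <- vapply(rs@lhs, paste, character(1), collapse = "\r")
  ord <- order(size, lhsKey, rs@rhs)
  newRuleSet(rs@lhs[ord], rs@rhs[ord], rs@quality[ord, , drop = FALSE],
             rs@info)
}

#' Generate association rules from frequent itemsets
#'
#' For every frequent itemset of size >= 2 and every single item y in it,
#' the rule (itemset \\ y) => y is emitted when confidence > `minConfidence`
#' AND lift > `minLift` AND support > `minSupport` (all strict). Metrics are
#' exact count ratios; rules are sorted by (itemset size, lexicographic lhs,
#' rhs).
#'
#' @param itemsets output of [aprioriFrequentItemsets()] over the same `tdb`.
#' @param tdb the [TransactionDB-class] the itemsets were mined from.
#' @param minSupport,minConfidence,minLift strict thresholds (defaults 0.01,
#'   0.5, 2 — the published settings).
#' @return an [AssociationRuleSet-class].
#' @export
generateRules <- function(itemsets, tdb, minSupport = 0.01,
                          minConfidence = 0.5, minLift = 2) {
  n <- nPatients(tdb)
  key <- itemsetKey(itemsets$items)
  countOf <- stats::setNames(itemsets$count, key)
  lhsL <- list(); rhsV <- character(0); qual <- list()
  big <- which(itemsets$size >= 2L)
  for (i in big) {
    set <- itemsets$items[[i]]
    cBoth <- itemsets$count[i]
    if (!(cBoth > minSupport * n)) next
    for (y in set) {
      lhs <- sort(setdiff(set, y))
      cLhs <- countOf[[paste(lhs, collapse = "\r")]]
      cRhs <- countOf[[y]]
      # downward closure guarantees both subsets are in the frequent table
      if (is.null(cLhs) || is.null(cRhs)) next
      conf <- cBoth / cLhs
      lift <- (cBoth * n) / (cLhs * cRhs)
      if (conf > minConfidence && lift > minLift) {
        lhsL[[length(lhsL) + 1L]] <- lhs
        rhsV <- c(rhsV, y)
        qual[[length(qual) + 1L]] <- data.frame(
          support = cBoth / n, confidence = conf, lift = lift,
          count = cBoth, lhsCount = cLhs, rhsCount = cRhs, n = n)
      }
    }
  }
  quality <- if (length(qual)) do.call(rbind, qual)
             else data.frame(support = numeric(0), confidence = numeric(0),
                             lift = numeric(0), count = integer(0),
                             lhsCount = integer(0), rhsCount = integer(0),
                             n = integer(0))
  rs <- newRuleSet(lhsL, rhsV, quality,
                   info = list(minSupport = minSupport,
                               minConfidence = minConfidence,
                               minLift = minLift, n = n))
  sortRules(rs)
}

#' Mine association rules from a transaction database
#'
#' Convenience wrapper: [aprioriFrequentItemsets()] followed by
#' [generateRules()].
#'
#' @inheritParams aprioriFrequentItemsets
#' @inheritParams generateRules
#' @return an [AssociationRuleSet-class].
#' @export
mineRules <- function(tdb, minSupport = 0.01, minConfidence = 0.5,
                      minLift = 2, maxSize = 3L) {
  its <- aprioriFrequentItemsets(tdb, minSupport = minSupport,
                                 maxSize = maxSize)
  generateRules(its, tdb, minSupport = minSupport,
                minConfidence = minConfidence, minLift = minLift)
}

#' Exhaustive brute-force rule enumeration (testing oracle)
#'
#' Enumerates every itemset of size 2..`maxSize` over the item universe and
#' every single-item consequent, computing supports by direct counting, with
#' the same strict filtering semantics as [generateRules()]. Quadratic
#' blow-up is guarded: at most 20 distinct items.
#'
#' @inheritParams mineRules
#' @return an [AssociationRuleSet-class].
#' @export
bruteForceRules <- function(tdb, minSupport = 0.01, minConfidence = 0.5,
                            minLift = 2, maxSize = 3L) {
  items <- itemLabels(tdb)
  if (length(items) > 20L)
    stop("brute force guard: more than 20 distinct items")
  n <- nPatients(tdb)
  emptyQ <- data.frame(support = numeric(0), confidence = numeric(0),
                       lift = numeric(0), count = integer(0),
                       lhsCount = integer(0), rhsCount = integer(0),
                       n = integer(0))
  if (n == 0L || length(items) < 2L)
    return(newRuleSet(list(), character(0), emptyQ))
  X <- as.matrix(Matrix::t(tdb@incidence))
  cnt <- function(set) sum(rowSums(X[, set, drop = FALSE]) == length(set))
  lhsL <- list(); rhsV <- character(0); qual <- list()
  for (k in 2:min(maxSize, length(items))) {
    sets <- utils::combn(sort(items), k, simplify = FALSE)
    for (set in sets) {
      cBoth <- cnt(set)
      if (!(cBoth > minSupport * n)) next
      for (y in set) {
        lhs <- setdiff(set, y)
        cLhs <- cnt(lhs); cRhs <- cnt(y)
        if (cLhs == 0L || cRhs == 0L) next
        conf <- cBoth / cLhs
        lift <- (cBoth * n) / (cLhs * cRhs)
        if (conf > minConfidence && lift > minLift) {
          lhsL[[length(lhsL) + 1L]] <- lhs
          rhsV <- c(rhsV, y)
          qual[[length(qual) + 1L]] <- data.frame(
            support = cBoth / n, confidence = conf, lift = lift,
            count = cBoth, lhsCount = cLhs, rhsCount = cRhs, n = n)
        }
      }
    }
  }
  quality <- if (length(qual)) do.call(rbind, qual) else emptyQ
  sortRules(newRuleSet(lhsL, rhsV, quality))
}

#' Keep one rule per frequent itemset
#'
#' Rules sharing the same combined itemset (lhs u rhs) describe the same
#' co-occurrence read in different directions; only one is kept — the one
#' with maximum confidence (ties: maximum lift, then lexicographically
#' smallest rhs). The result's `info$dedup` records the group count and the
#' dropped rules.
#'
#' @param rules an [AssociationRuleSet-class].
#' @return the deduplicated [AssociationRuleSet-class] (original order
#'   preserved among kept rules).
#' @export
dedupeByItemset <- function(rules) {
  nr <- length(rules@rhs)
  if (nr == 0L) return(rules)
  key <- vapply(seq_len(nr), function(i)
    paste(sort(c(rules@lhs[[i]], rules@rhs[i])), collapse = "\r"),
    character(1))
  keep <- logical(nr)
  for (grp in split(seq_len(nr), key)) {
    q <- rules@quality[grp, , drop = FALSE]
    best <- grp[order(-q$confidence, -q$lift, rules@rhs[grp])][1L]
    keep[best] <- TRUE
  }
  info <- rules@info
  info$dedup <- list(nGroups = length(unique(key)),
                     nDropped = sum(!keep),
                     dropped = as.data.frame(rules)[!keep, , drop = FALSE])
  newRuleSet(rules@lhs[keep], rules@rhs[keep],
             rules@quality[keep, , drop = FALSE], info)
}

#' Summary statistics of a rule set's metrics
#'
#' @param rules an [AssociationRuleSet-class].
#' @return data.frame with one row per metric (support, confidence, lift)
#'   and columns `min`, `max`, `mean` (full precision; round for display).
#'   An empty rule set yields a zero-row frame.
#' @export
summarizeRules <- function(rules) {
  q <- rules@quality
  if (!nrow(q))
    return(data.frame(metric = character(0), min = numeric(0),
                      max = numeric(0), mean = numeric(0)))
  do.call(rbind, lapply(c("support", "confidence", "lift"), function(mt)
    data.frame(metric = mt, min = min(q[[mt]]), max = max(q[[mt]]),
               mean = mean(q[[mt]]), stringsAsFactors = FALSE)))
}

#' @describeIn ruleQuality quality frame of a rule set
#' @export
setMethod("ruleQuality", "AssociationRuleSet", function(x) x@quality)

#' @describeIn itemLabels items participating in any rule
#' @export
setMethod("itemLabels", "AssociationRuleSet", function(x)
  sort(unique(c(unlist(x@lhs), x@rhs))))

#' @describeIn AssociationRuleSet-class number of rules
#' @param x an AssociationRuleSet.
#' @export
setMethod("length", "AssociationRuleSet", function(x) length(x@rhs))

#' Coerce a rule set to a data.frame
#'
#' @param x an [AssociationRuleSet-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @return data.frame with `lhs` (items `|`-joined), `rhs` and the quality
#'   columns at full precision.
#' @exportS3Method base::as.data.frame
#' @export
as.data.frame.AssociationRuleSet <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  out <- cbind(data.frame(
    lhs = vapply(x@lhs, paste, character(1), collapse = "|"),
    rhs = x@rhs, stringsAsFactors = FALSE), x@quality)
  rownames(out) <- NULL
  out
}

setMethod("as.data.frame", "AssociationRuleSet",
          as.data.frame.AssociationRuleSet)

#' @describeIn AssociationRuleSet-class display rules rounded to 2 decimals
#' @param object an AssociationRuleSet.
#' @export
setMethod("show", "AssociationRuleSet", function(object) {
  n <- length(object@rhs)
  cat("AssociationRuleSet with", n, "rule(s)\n")
  if (n) {
    df <- as.data.frame(object)[, c("lhs", "rhs", "support", "confidence",
                                    "lift")]
    df$support <- round(df$support, 2)
    df$confidence <- round(df$confidence, 2)
    df$lift <- round(df$lift, 2)
    print(utils::head(df, 20L))
    if (n > 20L) cat("... and", n - 20L, "more\n")
  }
})

#' Write rules as CSV (and optionally JSON)
#'
#' @param rules an [AssociationRuleSet-class].
#' @param path output CSV path (`lhs` items `|`-joined).
#' @param jsonPath optional JSON twin.
#' @return `path`, invisibly.
#' @export
writeRulesCSV <- function(rules, path, jsonPath = NULL) {
  df <- as.data.frame(rules)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(df, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
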
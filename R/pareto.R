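#' Rank diseases by frequency with cumulative coverage
#'
#' Diseases are sorted by patient count in decreasing order (ties broken
#' lexicographically by label, for determinism) and the cumulative
#' proportion is computed under the chosen denominator.
#'
#' Under `"disease_instances"` (default) the denominator is the sum of all
#' per-disease counts, so the cumulative proportion ends at exactly 1. Under
#' `"patients_with_comorbidity"` it is the number of patients with at least
#' one comorbidity; because multimorbid patients are counted once per
#' disease, the cumulative value can then exceed 1.
#'
#' @param tdb a [TransactionDB-class].
#' @param denominator `"disease_instances"` or `"patients_with_comorbidity"`.
#' @return data.frame with columns `rank`, `category`, `count`,
#'   `cumulative`; zero-count categories are omitted. An empty ranking (all
#'   transactions empty) is returned with a warning.
#' @export
rankDiseases <- function(tdb,
                         denominator = c("disease_instances",
                                         "patients_with_comorbidity")) {
  denominator <- match.arg(denominator)
  counts <- itemCounts(tdb)
  counts <- counts[counts > 0L]
  if (!length(counts)) {
    warning("all transactions are empty; returning an empty ranking")
    return(data.frame(rank = integer(0), category = character(0),
                      count = integer(0), cumulative = numeric(0)))
  }
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  denom <- switch(denominator,
    disease_instances = sum(counts),
    patients_with_comorbidity =
      sum(Matrix::colSums(tdb@incidence) > 0))
  data.frame(rank = seq_along(counts), category = names(counts),
             count = as.integer(counts),
             cumulative = cumsum(as.numeric(counts)) / denom,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Identify the Pareto head of predominant diseases
#'
#' The head is the shortest prefix of the ranking whose cumulative
#' proportion reaches the threshold (default 0.80, the 80-20 rule). The
#' achieved coverage may exceed the threshold.
#'
#' @param ranked data.frame from [rankDiseases()] (or a
#'   [TransactionDB-class], which is ranked first with defaults).
#' @param threshold proportion in (0, 1].
#' @param denominator recorded in the result for provenance.
#' @return a [ParetoResult-class].
#' @export
paretoHead <- function(ranked, threshold = 0.80,
                       denominator = "disease_instances") {
  if (methods::is(ranked, "TransactionDB"))
    ranked <- rankDiseases(ranked, denominator)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("threshold must be a proportion in (0, 1]")
  hit <- which(ranked$cumulative >= threshold - 1e-12)
  headSize <- if (length(hit)) hit[1L] else nrow(ranked)
  coverage <- if (nrow(ranked)) ranked$cumulative[headSize] else 0
  if (!nrow(ranked)) headSize <- 0L
  methods::new("ParetoResult", ranked = ranked, threshold = threshold,
               headSize = as.integer(headSize), coverage = as.numeric(coverage),
               denominator = denominator)
}

#' Categories in the Pareto head
#' @param x a [ParetoResult-class].
#' @return character vector of the head's category labels, in rank order.
#' @export
headCategories <- function(x) {
  stopifnot(methods::is(x, "ParetoResult"))
  x@ranked$category[seq_len(x@headSize)]
}

#' Write a ranked disease table as CSV
#' @param ranked data.frame from [rankDiseases()] or a [ParetoResult-class].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeRankedCSV <- function(ranked, path) {
  if (methods::is(ranked, "ParetoResult")) ranked <- ranked@ranked
  utils::write.csv(ranked, path, row.names = FALSE)
  invisible(path)
}

#' @describeIn ParetoResult-class compact display
#' @param object a ParetoResult.
#' @export
setMethod("show", "ParetoResult", function(object) {
  cat(sprintf(
    "ParetoResult: %d of %d diseases cover %.1f%% (threshold %.0f%%, %s)\n",
    object@headSize, nrow(object@ranked), 100 * object@coverage,
    100 * object@threshold, object@denominator))
})
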
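#' Read raw EMR diagnosis records
#'
#' One record per row. Blank mandatory cells are preserved as missing ("")
#' rather than dropped; eligibility filtering is a separate step
#' ([filterCohort()]).
#'
#' @param path CSV with header; required columns `case_number`, `gender`,
#'   `age`, `hospital`, `icd10_codes`.
#' @param sep field separator (default ",").
#' @param codeDelim delimiter inside the `icd10_codes` cell (default ";").
#' @return data.frame of diagnosis records; the diagnosis-code column keeps
#'   the raw `codeDelim`-joined string, with `attr(,"codeDelim")` recording
#'   the delimiter.
#' @export
readEMR <- function(path, sep = ",", codeDelim = ";") {
  if (!file.exists(path)) stop("cannot read EMR file: ", path)
  rec <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  required <- c("case_number", "gender", "age", "hospital", "icd10_codes")
  if (length(miss <- setdiff(required, names(rec))))
    stop("EMR file lacks required column(s): ", paste(miss, collapse = ", "))
  rec$age <- suppressWarnings(as.integer(rec$age))
  attr(rec, "codeDelim") <- codeDelim
  rec
}

splitCodes <- function(records) {
  delim <- attr(records, "codeDelim")
  if (is.null(delim)) delim <- ";"
  strsplit(records$icd10_codes, delim, fixed = TRUE)
}

#' Apply cohort eligibility and cleaning rules
#'
#' Keeps records that (i) have non-missing gender, hospital and case number,
#' (ii) carry at least one index (lung cancer) code, (iii) are at least
#' `minAge` years old, and (iv) are the first occurrence of their composite
#' primary key (case number, gender, age). Each excluded record is counted
#' under exactly one reason, the first matching one in that fixed order, so
#' the exclusion report is deterministic.
#'
#' @param records data.frame from [readEMR()] or [generateCohort()].
#' @param catalog a [DiseaseCatalog-class] (supplies the index codes).
#' @param minAge minimum age in years (default 65).
#' @return list with `records` (the kept rows, original order) and `report`,
#'   a named integer vector: `n_in`, `missing_field`, `no_index_code`,
#'   `under_age`, `duplicate_key`, `kept`.
#' @export
filterCohort <- function(records, catalog, minAge = 65) {
  n <- nrow(records)
  if (n == 0L) {
    report <- c(n_in = 0L, missing_field = 0L, no_index_code = 0L,
                under_age = 0L, duplicate_key = 0L, kept = 0L)
    return(list(records = records, report = report))
  }
  missingField <- !nzchar(records$gender) | is.na(records$gender) |
    !nzchar(records$hospital) | is.na(records$hospital) |
    !nzchar(records$case_number) | is.na(records$case_number)
  codes <- splitCodes(records)
  hasIndex <- vapply(codes, function(cs)
    any(cs %in% catalog@indexCodes), logical(1))
  underAge <- is.na(records$age) | records$age < minAge

  reason <- rep(NA_character_, n)
  reason[underAge] <- "under_age"
  reason[!hasIndex] <- "no_index_code"
  reason[missingField] <- "missing_field"   # highest precedence last

  eligible <- is.na(reason)
  key <- compositeKey(records)
  dup <- eligible & duplicated(ifelse(eligible, key, paste0(".row", seq_len(n))))
  reason[dup] <- "duplicate_key"
  keep <- is.na(reason)

  report <- c(
    n_in = n,
    missing_field = sum(reason == "missing_field", na.rm = TRUE),
    no_index_code = sum(reason == "no_index_code", na.rm = TRUE),
    under_age = sum(reason == "under_age", na.rm = TRUE),
    duplicate_key = sum(reason == "duplicate_key", na.rm = TRUE),
    kept = sum(keep))
  kept <- records[keep, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "codeDelim") <- attr(records, "codeDelim")
  list(records = kept, report = report)
}

#' Build the transaction database from filtered records
#'
#' Each patient's transaction is the set of catalog categories among their
#' diagnosis codes, excluding the index (lung cancer) codes. Codes absent
#' from the catalog are dropped and tallied in the result's `info`
#' (`unknownCodes`). Duplicate categories collapse to one set element;
#' patients whose only diagnosis is the index disease yield an empty
#' transaction and still count towards the patient denominator.
#'
#' @param records filtered records ([filterCohort()]).
#' @param catalog a [DiseaseCatalog-class].
#' @return a [TransactionDB-class] whose item universe is the full catalog
#'   category set (zero-count categories retained).
#' @export
buildTransactions <- function(records, catalog) {
  codes <- splitCodes(records)
  unknown <- 0L
  sets <- lapply(codes, function(cs) {
    cs <- setdiff(cs, catalog@indexCodes)
    cat_ <- codeToCategory(catalog, cs)
    unknown <<- unknown + sum(is.na(cat_))
    sort(unique(cat_[!is.na(cat_)]))
  })
  names(sets) <- compositeKey(records)
  if (unknown > 0L)
    warning(unknown, " diagnosis code(s) absent from the catalog were dropped")
  TransactionDB(sets, items = sort(catalogCategories(catalog)),
                info = list(unknownCodes = unknown))
}

#' Comorbidity-count distribution and per-disease burden
#'
#' Summarises the transaction database as (i) the histogram of
#' comorbidity counts per patient (0 .. max) with proportions summing to 1,
#' and (ii) a per-disease table: among patients carrying disease D, the
#' percentage whose transaction holds exactly one comorbidity (D alone)
#' versus two or more, and the mean comorbidity count of those patients.
#'
#' @param tdb a [TransactionDB-class].
#' @param meanIncludesSelf if `TRUE` (default) the per-disease mean counts
#'   the patient's full transaction size (D included); if `FALSE`, size - 1.
#' @return list with `histogram` (data.frame `n_comorbidities`, `count`,
#'   `proportion`) and `perDisease` (data.frame `category`, `n_cases`,
#'   `single_pct`, `multiple_pct`, `mean_comorbidities`), the latter ordered
#'   by decreasing `n_cases`.
#' @export
comorbidityDistribution <- function(tdb, meanIncludesSelf = TRUE) {
  sizes <- as.integer(Matrix::colSums(tdb@incidence))
  n <- length(sizes)
  maxSize <- if (n) max(sizes) else 0L
  cnt <- tabulate(sizes + 1L, nbins = maxSize + 1L)
  histogram <- data.frame(n_comorbidities = 0:maxSize, count = cnt,
                          proportion = if (n) cnt / n else numeric(maxSize + 1L))

  counts <- itemCounts(tdb)
  counts <- counts[counts > 0L]
  perDisease <- do.call(rbind, lapply(names(counts), function(d) {
    has <- tdb@incidence[d, ]
    sz <- sizes[has]
    data.frame(category = d, n_cases = length(sz),
               single_pct = 100 * mean(sz == 1L),
               multiple_pct = 100 * mean(sz >= 2L),
               mean_comorbidities =
                 mean(sz) - if (meanIncludesSelf) 0 else 1,
               stringsAsFactors = FALSE)
  }))
  if (is.null(perDisease))
    perDisease <- data.frame(category = character(0), n_cases = integer(0),
                             single_pct = numeric(0), multiple_pct = numeric(0),
                             mean_comorbidities = numeric(0))
  perDisease <- perDisease[order(-perDisease$n_cases, perDisease$category), ]
  rownames(perDisease) <- NULL
  list(histogram = histogram, perDisease = perDisease)
}
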
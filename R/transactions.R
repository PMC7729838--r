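#' Build a TransactionDB from a list of label sets
#'
#' @param transactions named list of character vectors, one per patient; an
#'   element may be empty (a patient with zero comorbidities).
#' @param items item universe. Defaults to the sorted union of the labels
#'   present; pass the full catalog category set to keep zero-count diseases.
#' @param info optional bookkeeping list.
#' @return a [TransactionDB-class].
#' @export
TransactionDB <- function(transactions, items = NULL, info = list()) {
  keys <- names(transactions)
  if (is.null(keys)) keys <- if (length(transactions))
    paste0("T", seq_along(transactions)) else character(0)
  labs <- unique(unlist(transactions, use.names = FALSE))
  if (is.null(items)) items <- sort(labs)
  if (length(bad <- setdiff(labs, items)))
    stop("transaction labels outside the item universe: ",
         paste(bad, collapse = ", "))
  i <- match(unlist(transactions, use.names = FALSE), items)
  j <- rep(seq_along(transactions), lengths(transactions))
  inc <- Matrix::sparseMatrix(
    i = i, j = j, dims = c(length(items), length(transactions)),
    dimnames = list(items, keys), repr = "C")
  inc <- methods::as(inc, "nMatrix")   # collapse duplicate (item, patient)
  methods::new("TransactionDB", incidence = methods::as(inc, "CsparseMatrix"),
               info = info)
}

#' @describeIn nPatients number of transactions in the database
#' @export
setMethod("nPatients", "TransactionDB",
          function(x) ncol(x@incidence))

#' @describeIn itemLabels item universe of the database
#' @export
setMethod("itemLabels", "TransactionDB",
          function(x) rownames(x@incidence))

#' @describeIn itemCounts patient count per item
#' @export
setMethod("itemCounts", "TransactionDB", function(x) {
  cnt <- Matrix::rowSums(x@incidence)
  stats::setNames(as.integer(cnt), rownames(x@incidence))
})

#' @describeIn transactionList per-patient label sets
#' @export
setMethod("transactionList", "TransactionDB", function(x) {
  items <- rownames(x@incidence)
  m <- x@incidence
  lapply(stats::setNames(seq_len(ncol(m)), colnames(m)),
         function(j) sort(items[m[, j]]))
})

#' @describeIn TransactionDB-class number of transactions
#' @param x a TransactionDB.
#' @export
setMethod("length", "TransactionDB", function(x) ncol(x@incidence))

#' @describeIn TransactionDB-class compact display
#' @param object a TransactionDB.
#' @export
setMethod("show", "TransactionDB", function(object) {
  sz <- Matrix::colSums(object@incidence)
  cat("TransactionDB:", ncol(object@incidence), "patients,",
      nrow(object@incidence), "items;",
      sum(sz == 0), "patients without comorbidities\n")
})

#' Write transactions in basket text format
#'
#' One line per patient: `key<TAB>item1,item2,...` (empty item list for
#' zero-comorbidity patients).
#'
#' @param tdb a [TransactionDB-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBaskets <- function(tdb, path) {
  tl <- transactionList(tdb)
  lines <- paste0(names(tl), "\t",
                  vapply(tl, paste, character(1), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read transactions from basket text format
#'
#' @param path file written by [writeBaskets()] or compatible.
#' @param items optional item universe.
#' @return a [TransactionDB-class].
#' @export
readBaskets <- function(path, items = NULL) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(parts, `[`, character(1), 1L)
  sets <- lapply(parts, function(p)
    if (length(p) < 2L || !nzchar(p[2L])) character(0)
    else strsplit(p[2L], ",", fixed = TRUE)[[1L]])
  names(sets) <- keys
  TransactionDB(sets, items = items)
}
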
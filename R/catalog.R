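#' Construct a disease catalog
#'
#' @param entries data.frame with columns `icd10_code` and `category`
#'   (a `chapter` column is added from the code if absent).
#' @param indexCodes character vector of ICD-10 codes identifying the index
#'   disease (default `"C34"`, lung cancer).
#' @return a [DiseaseCatalog-class].
#' @export
diseaseCatalog <- function(entries, indexCodes = "C34") {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (!"chapter" %in% names(entries))
    entries$chapter <- icdChapter(entries$icd10_code)
  methods::new("DiseaseCatalog", entries = entries,
               indexCodes = as.character(indexCodes))
}

#' The packaged default morbidity catalog
#'
#' 31 morbidity categories observed in older lung-cancer patients, each with
#' one representative ICD-10 code, plus lung cancer (C34) as the index
#' disease. Ten codes (I10, I20, I25, I25.1, I25.5, I31, I50, I63, J18, E11)
#' are the standard codes for their categories; the remaining categories are
#' assigned a representative code from the matching ICD-10 block.
#'
#' @return a [DiseaseCatalog-class].
#' @export
defaultCatalog <- function() {
  tab <- utils::read.csv(extdata("reference_morbidity_counts.csv"),
                         stringsAsFactors = FALSE)
  diseaseCatalog(data.frame(icd10_code = tab$icd10_code,
                            category = tab$category,
                            stringsAsFactors = FALSE))
}

#' Read a disease catalog from a two-column CSV
#'
#' @param path CSV with columns `icd10_code,category` (optional `chapter`).
#' @param indexCodes index-disease codes, default C34.
#' @return a [DiseaseCatalog-class].
#' @export
readCatalog <- function(path, indexCodes = "C34") {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("icd10_code", "category") %in% names(tab)))
    stop("catalog file must have columns 'icd10_code' and 'category'")
  diseaseCatalog(tab, indexCodes = indexCodes)
}

#' Map ICD-10 codes to category labels
#'
#' @param catalog a [DiseaseCatalog-class].
#' @param codes character vector of ICD-10 codes.
#' @return character vector of categories; NA for codes not in the catalog
#'   (index codes included map to NA as well — they are not comorbidities).
#' @export
codeToCategory <- function(catalog, codes) {
  catalog@entries$category[match(codes, catalog@entries$icd10_code)]
}

#' Category labels of a catalog
#' @param catalog a [DiseaseCatalog-class].
#' @return character vector.
#' @export
catalogCategories <- function(catalog) catalog@entries$category

#' ICD-10 chapter tag per category
#' @param catalog a [DiseaseCatalog-class].
#' @return named character vector (names are categories).
#' @export
catalogChapters <- function(catalog) {
  stats::setNames(catalog@entries$chapter, catalog@entries$category)
}

#' @describeIn DiseaseCatalog-class compact display
#' @param object a DiseaseCatalog.
#' @export
setMethod("show", "DiseaseCatalog", function(object) {
  cat("DiseaseCatalog:", nrow(object@entries), "categories; index code(s):",
      paste(object@indexCodes, collapse = ", "), "\n")
})
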
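# Internal helpers.

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# ICD-10 chapter tag from a code ("I25.1" -> "IX Circulatory").
# Covers the chapters that occur among the packaged morbidity categories;
# anything else falls back to the code's letter.
icdChapter <- function(code) {
  vapply(code, function(cd) {
    letter <- toupper(substr(cd, 1, 1))
    num <- suppressWarnings(as.integer(substr(cd, 2, 3)))
    if (is.na(num)) num <- 0L
    if (letter %in% c("A", "B")) return("I Infectious")
    if (letter == "C" || (letter == "D" && num <= 48)) return("II Neoplasms")
    if (letter == "D") return("III Blood")
    if (letter == "E") return("IV Endocrine/metabolic")
    if (letter == "F") return("V Mental")
    if (letter == "G") return("VI Nervous")
    if (letter == "I") return("IX Circulatory")
    if (letter == "J") return("X Respiratory")
    if (letter == "K") return("XI Digestive")
    if (letter == "N") return("XIV Genitourinary")
    letter
  }, character(1), USE.NAMES = FALSE)
}

xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# Composite primary key used for deduplication: case number + gender + age.
compositeKey <- function(records) {
  paste(records$case_number, records$gender, records$age, sep = "|")
}

extdata <- function(file) {
  system.file("extdata", file, package = "comorbid", mustWork = TRUE)
}
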
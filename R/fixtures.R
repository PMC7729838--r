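#' Published per-disease counts of the reference cohort
#'
#' The 31 morbidity categories observed among 1510 older lung-cancer
#' patients in a 2018 provincial EMR study in Northeast China, with each
#' category's patient count and the percentage of those patients carrying a
#' single versus multiple comorbidities. These published summary statistics
#' anchor the synthetic generator's default marginals and serve as frozen
#' expectations in tests; the underlying patient-level records are not
#' publicly available.
#'
#' @return data.frame with columns `category`, `icd10_code`, `n_cases`,
#'   `single_pct`, `multiple_pct`, ordered by decreasing count.
#' @export
referenceMorbidityCounts <- function() {
  utils::read.csv(extdata("reference_morbidity_counts.csv"),
                  stringsAsFactors = FALSE)
}

#' Published demographic summary of the reference cohort
#'
#' Cohort-level counts and percentages (total n = 1510): age bands, gender,
#' nationality, occupation, marital status and the comorbidity-count
#' distribution. Note the published comorbidity-count rows sum to 1530, not
#' 1510; percentages are relative to 1510.
#'
#' @return data.frame with columns `characteristic`, `level`, `n`, `pct`.
#' @export
referenceCohortSummary <- function() {
  utils::read.csv(extdata("reference_cohort_summary.csv"),
                  stringsAsFactors = FALSE)
}

#' The 41 published association rules of the reference cohort
#'
#' The printed rule table (support, confidence, lift rounded to two
#' decimals) as an [AssociationRuleSet-class]. Only the rounded metrics are
#' available — the underlying counts are not — so count columns are absent
#' from the quality frame.
#'
#' @return an [AssociationRuleSet-class] of 41 rules, in published order
#'   (`info$rule_no` keeps the published numbering).
#' @export
referenceRules <- function() {
  tab <- utils::read.csv(extdata("reference_rules.csv"),
                         stringsAsFactors = FALSE)
  newRuleSet(
    lhs = lapply(strsplit(tab$lhs, "|", fixed = TRUE), sort),
    rhs = tab$rhs,
    quality = data.frame(support = tab$support,
                         confidence = tab$confidence, lift = tab$lift),
    info = list(rule_no = tab$rule_no, source = "published reference table"))
}

#' Demonstration cohort configuration
#'
#' A synthetic stand-in for the reference cohort: n = 1510, published
#' demographics and disease marginals, and a handful of planted conditional
#' dependencies patterned on the strongest published rules (e.g. the
#' atherosclerotic heart disease + ischemic cardiomyopathy => heart failure
#' triad at conditional probability 0.92). Entirely synthetic: it emulates
#' the cohort's statistical shape, not its patients.
#'
#' @param nPatients cohort size (default 1510).
#' @param seed RNG seed (default 42).
#' @param ... further arguments passed to [cohortConfig()].
#' @return a [CohortConfig-class].
#' @export
demoConfig <- function(nPatients = 1510, seed = 42L, ...) {
  cohortConfig(
    nPatients = nPatients, seed = seed,
    plantedRules = list(
      plantedDependency("Degenerative diseases of the nervous system",
                        "Cerebral infarction", 0.71),
      plantedDependency("Chronic ischemic heart disease",
                        "Heart failure", 0.62),
      plantedDependency("Angina pectoris", "Heart failure", 0.69),
      plantedDependency(c("Disorders of glycoprotein metabolism",
                          "Hyponatremia"), "Anemia", 0.60),
      plantedDependency(c("Atherosclerotic heart disease",
                          "Ischemic cardiomyopathy"),
                        "Heart failure", 0.92)),
    ...)
}
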
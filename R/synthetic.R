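#' Default disease marginal prevalences
#'
#' Marginal prevalence per morbidity category, taken as the published
#' per-disease patient counts of the reference cohort divided by its size
#' (n = 1510); see [referenceMorbidityCounts()].
#'
#' @return named numeric vector of prevalences in (0, 1).
#' @export
defaultMarginals <- function() {
  tab <- utils::read.csv(extdata("reference_morbidity_counts.csv"),
                         stringsAsFactors = FALSE)
  stats::setNames(tab$n_cases / 1510, tab$category)
}

#' A planted conditional dependency
#'
#' When every disease in `source` is present in a simulated patient, the
#' target's marginal Bernoulli draw is overridden by a fresh
#' Bernoulli(`prob`) draw. `prob` may be below the target's marginal
#' (dependencies can suppress as well as promote).
#'
#' @param source character vector of 1 or 2 disease labels.
#' @param target single disease label, not in `source`.
#' @param prob conditional probability P(target | all of source present).
#' @return a list usable in the `plantedRules` of [cohortConfig()].
#' @export
plantedDependency <- function(source, target, prob) {
  list(source = as.character(source), target = as.character(target),
       prob = as.numeric(prob))
}

#' Configure a synthetic EMR cohort
#'
#' Defaults reproduce the published reference cohort's structure: n = 1510,
#' age bands 65-74 / 75-84 / 85+ at 74.4% / 21.8% / 3.8%, 60.2% male, and
#' per-disease marginals from [defaultMarginals()].
#'
#' @param nPatients number of base records.
#' @param ageDistribution data.frame(lo, hi, prop); proportions sum to 1.
#'   Ages are drawn uniformly within the band; the open-ended 85+ band is
#'   capped at 95.
#' @param maleFraction probability a patient is male.
#' @param diseaseMarginals named numeric vector of marginal prevalences.
#' @param plantedRules list of [plantedDependency()] items, applied in order.
#' @param missingFieldRate proportion of records with one mandatory field
#'   (gender, hospital or case number) blanked.
#' @param duplicateKeyRate proportion of records re-emitted with an
#'   identical primary key.
#' @param seed integer RNG seed.
#' @return a validated [CohortConfig-class].
#' @export
cohortConfig <- function(nPatients = 1510,
                         ageDistribution = data.frame(
                           lo = c(65, 75, 85), hi = c(74, 84, 95),
                           prop = c(0.744, 0.218, 0.038)),
                         maleFraction = 0.602,
                         diseaseMarginals = defaultMarginals(),
                         plantedRules = list(),
                         missingFieldRate = 0,
                         duplicateKeyRate = 0,
                         seed = 1L) {
  obj <- methods::new("CohortConfig",
    nPatients = as.integer(nPatients),
    ageDistribution = as.data.frame(ageDistribution),
    maleFraction = as.numeric(maleFraction),
    diseaseMarginals = diseaseMarginals,
    plantedRules = plantedRules,
    missingFieldRate = as.numeric(missingFieldRate),
    duplicateKeyRate = as.numeric(duplicateKeyRate),
    seed = as.integer(seed))
  obj
}

#' Read a cohort configuration from YAML or JSON
#'
#' Recognised top-level keys mirror the arguments of [cohortConfig()], in
#' snake_case (`n_patients`, `male_fraction`, `disease_marginals`,
#' `planted_rules` with `source`/`target`/`prob`, `missing_field_rate`,
#' `duplicate_key_rate`, `seed`, `age_distribution` with `lo`/`hi`/`prop`).
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a [CohortConfig-class].
#' @export
readCohortConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$n_patients)) args$nPatients <- cfg$n_patients
  if (!is.null(cfg$male_fraction)) args$maleFraction <- cfg$male_fraction
  if (!is.null(cfg$disease_marginals))
    args$diseaseMarginals <- unlist(cfg$disease_marginals)
  if (!is.null(cfg$age_distribution))
    args$ageDistribution <- as.data.frame(cfg$age_distribution)
  if (!is.null(cfg$planted_rules))
    args$plantedRules <- lapply(cfg$planted_rules, function(r)
      plantedDependency(r$source, r$target, r$prob))
  if (!is.null(cfg$missing_field_rate))
    args$missingFieldRate <- cfg$missing_field_rate
  if (!is.null(cfg$duplicate_key_rate))
    args$duplicateKeyRate <- cfg$duplicate_key_rate
  if (!is.null(cfg$seed)) args$seed <- cfg$seed
  do.call(cohortConfig, args)
}

# categorical demographic pools with reference-cohort proportions
.demographicPool <- function(field) {
  tab <- utils::read.csv(extdata("reference_cohort_summary.csv"),
                         stringsAsFactors = FALSE)
  tab <- tab[tab$characteristic == field, ]
  list(levels = tab$level, prob = tab$n / sum(tab$n))
}

#' Generate a synthetic EMR cohort
#'
#' Produces one row per base patient (plus duplicate rows per
#' `duplicateKeyRate`). Every record carries the lung-cancer index code C34;
#' comorbidity codes are drawn as independent Bernoulli(marginal) variables
#' and then overridden by the planted dependencies in list order. Records
#' selected for corruption have exactly one of gender, hospital or case
#' number blanked. Corruption and duplication draws happen after all disease
#' draws, so toggling the defect rates does not alter the disease pattern of
#' the uncorrupted records. Output is reproducible for a fixed seed.
#'
#' @param config a [CohortConfig-class].
#' @param catalog a [DiseaseCatalog-class] supplying ICD-10 codes for the
#'   configured categories (default [defaultCatalog()]). Categories without
#'   a catalog code are emitted under a synthetic `SYN##` code.
#' @return data.frame with columns `case_number, gender, age, hospital,
#'   nationality, occupation, marital_status, icd10_codes` (codes
#'   `;`-separated), one row per emitted record.
#' @export
generateCohort <- function(config, catalog = defaultCatalog()) {
  v <- .validCohortConfig(config)
  if (!isTRUE(v)) stop("invalid cohort configuration: ",
                       paste(v, collapse = "; "))
  n <- config@nPatients
  marg <- config@diseaseMarginals
  cats <- names(marg)
  code <- catalog@entries$icd10_code[match(cats, catalog@entries$category)]
  code[is.na(code)] <- sprintf("SYN%02d", seq_along(code)[is.na(code)])

  withLocalSeed(config@seed, {
    ad <- config@ageDistribution
    band <- sample.int(nrow(ad), n, replace = TRUE, prob = ad$prop)
    age <- ad$lo[band] +
      floor(stats::runif(n) * (ad$hi[band] - ad$lo[band] + 1L))
    gender <- ifelse(stats::runif(n) < config@maleFraction, "male", "female")
    hospital <- sprintf("H%02d", sample.int(20L, n, replace = TRUE))
    nat <- .demographicPool("nationality")
    occ <- .demographicPool("occupation")
    mar <- .demographicPool("marital_status")
    nationality <- sample(nat$levels, n, replace = TRUE, prob = nat$prob)
    occupation <- sample(occ$levels, n, replace = TRUE, prob = occ$prob)
    marital <- sample(mar$levels, n, replace = TRUE, prob = mar$prob)

    # independent marginal draws, then conditional overrides in list order
    present <- matrix(stats::runif(n * length(marg)) <
                        rep(marg, each = n), nrow = n,
                      dimnames = list(NULL, cats))
    for (r in config@plantedRules) {
      hit <- rowSums(present[, r$source, drop = FALSE]) == length(r$source)
      if (any(hit))
        present[hit, r$target] <- stats::runif(sum(hit)) < r$prob
    }

    caseno <- sprintf("P%06d", seq_len(n))
    codesPerPatient <- apply(present, 1L, function(p)
      paste(c("C34", code[p]), collapse = ";"))
    rec <- data.frame(case_number = caseno, gender = gender,
                      age = as.integer(age), hospital = hospital,
                      nationality = nationality, occupation = occupation,
                      marital_status = marital,
                      icd10_codes = codesPerPatient,
                      stringsAsFactors = FALSE)

    # data-quality defects, drawn after all disease draws
    nCorrupt <- round(config@missingFieldRate * n)
    corrupted <- if (nCorrupt > 0) sample.int(n, nCorrupt) else integer(0)
    if (nCorrupt > 0) {
      fld <- sample(c("gender", "hospital", "case_number"),
                    nCorrupt, replace = TRUE)
      for (k in seq_len(nCorrupt)) rec[corrupted[k], fld[k]] <- ""
    }
    nDup <- round(config@duplicateKeyRate * n)
    if (nDup > 0) {
      pool <- setdiff(seq_len(n), corrupted)
      dup <- if (length(pool) >= nDup) sample(pool, nDup)
             else sample.int(n, nDup)
      rec <- rbind(rec, rec[dup, , drop = FALSE])
      rownames(rec) <- NULL
    }
    rec
  })
}

#' Write a synthetic cohort as EMR CSV with a JSON manifest
#'
#' The sidecar manifest (`<path>.manifest.json`) records the configuration,
#' the seed, and — for every planted dependency whose structure is
#' enumerable — the analytic support/confidence/lift of the implied rule.
#'
#' @param records data.frame from [generateCohort()].
#' @param path output CSV path.
#' @param config the [CohortConfig-class] used (optional; enables the
#'   manifest).
#' @return `path`, invisibly.
#' @export
writeEMR <- function(records, path, config = NULL) {
  utils::write.csv(records, path, row.names = FALSE, quote = TRUE)
  if (!is.null(config)) {
    planted <- lapply(config@plantedRules, function(r) {
      metrics <- tryCatch(
        as.list(expectedRuleMetrics(config, r$source, r$target)),
        error = function(e) NULL)
      list(source = r$source, target = r$target, prob = r$prob,
           expected = metrics)
    })
    manifest <- list(
      n_patients = config@nPatients,
      male_fraction = config@maleFraction,
      age_distribution = config@ageDistribution,
      disease_marginals = as.list(config@diseaseMarginals),
      missing_field_rate = config@missingFieldRate,
      duplicate_key_rate = config@duplicateKeyRate,
      seed = config@seed,
      planted_rules = planted)
    jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Analytic rule metrics implied by a cohort configuration
#'
#' Computes the exact population-level support P(X,Y), confidence P(Y|X) and
#' lift P(X,Y)/(P(X) P(Y)) that a rule X => Y has under the generative model
#' of `config`, by exhaustive enumeration of the joint law of the involved
#' diseases (the queried labels plus, transitively, the sources of any
#' planted dependency targeting them). Serves as the independent oracle for
#' planted-rule recovery tests.
#'
#' @param config a [CohortConfig-class].
#' @param lhs character vector of disease labels (the rule antecedent).
#' @param rhs single disease label (the consequent).
#' @return named numeric vector `c(support, confidence, lift)`.
#' @export
expectedRuleMetrics <- function(config, lhs, rhs) {
  marg <- config@diseaseMarginals
  labs <- c(lhs, rhs)
  if (length(bad <- setdiff(labs, names(marg))))
    stop("unknown disease label(s): ", paste(bad, collapse = ", "))
  if (rhs %in% lhs) stop("rhs must not appear in lhs")

  # transitive closure over dependency sources
  S <- unique(labs)
  repeat {
    add <- unlist(lapply(config@plantedRules, function(r)
      if (r$target %in% S) r$source else NULL))
    add <- setdiff(add, S)
    if (!length(add)) break
    S <- c(S, add)
  }
  if (length(S) > 15L)
    stop("dependency structure involves ", length(S),
         " diseases; too large for exact enumeration")

  states <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(S))))
  colnames(states) <- S
  condProb <- function(d, state) {
    p <- marg[[d]]
    for (r in config@plantedRules)       # last applicable override wins
      if (identical(r$target, d) && all(state[r$source])) p <- r$prob
    p
  }
  probs <- apply(states, 1L, function(state) {
    prod(vapply(S, function(d) {
      p <- condProb(d, state)
      if (state[[d]]) p else 1 - p
    }, numeric(1)))
  })
  hasAll <- function(set) rowSums(states[, set, drop = FALSE]) == length(set)
  pBoth <- sum(probs[hasAll(c(lhs, rhs))])
  pLhs <- sum(probs[hasAll(lhs)])
  pRhs <- sum(probs[hasAll(rhs)])
  if (pLhs == 0) stop("P(lhs) = 0: confidence undefined")
  if (pRhs == 0) stop("P(rhs) = 0: lift undefined")
  c(support = pBoth, confidence = pBoth / pLhs,
    lift = pBoth / (pLhs * pRhs))
}

#' @describeIn CohortConfig-class compact display
#' @param object a CohortConfig.
#' @export
setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nPatients, "patients,",
      length(object@diseaseMarginals), "diseases,",
      length(object@plantedRules), "planted dependencies, seed",
      object@seed, "\n")
})
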
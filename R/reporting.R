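#' Rule-by-morbidity heatmap matrix
#'
#' One row per (deduplicated) rule, one column per participating morbidity;
#' the cell carries the rule's metric value in every column taking part in
#' the rule, with a role marker distinguishing LHS items from the single RHS
#' item (direction is co-occurrence, not causation). Cells for morbidities
#' not in the rule are NA.
#'
#' @param rules an [AssociationRuleSet-class] (deduplicate first with
#'   [dedupeByItemset()] if rules may share itemsets).
#' @param metric one of "support", "confidence", "lift".
#' @param columnOrder optional character vector fixing the column order
#'   (e.g. Pareto rank order); defaults to decreasing participation count.
#' @return list with `values` (numeric matrix), `roles` (character matrix,
#'   "lhs"/"rhs"/NA) and `metric`. Empty rule set: zero-row matrices with a
#'   warning.
#' @export
ruleHeatmap <- function(rules, metric = c("support", "confidence", "lift"),
                        columnOrder = NULL) {
  metric <- match.arg(metric)
  nr <- length(rules@rhs)
  if (nr == 0L) {
    warning("empty rule set: no heatmap produced")
    m <- matrix(numeric(0), 0, 0)
    return(list(values = m, roles = matrix(character(0), 0, 0),
                metric = metric))
  }
  part <- c(unlist(rules@lhs), rules@rhs)
  cols <- if (is.null(columnOrder)) {
    tab <- sort(table(part), decreasing = TRUE)
    names(tab)
  } else intersect(columnOrder, unique(part))
  rows <- vapply(seq_len(nr), function(i)
    paste0(paste(rules@lhs[[i]], collapse = " + "), " => ", rules@rhs[i]),
    character(1))
  values <- matrix(NA_real_, nr, length(cols),
                   dimnames = list(rows, cols))
  roles <- matrix(NA_character_, nr, length(cols),
                  dimnames = list(rows, cols))
  v <- rules@quality[[metric]]
  for (i in seq_len(nr)) {
    values[i, rules@lhs[[i]]] <- v[i]
    roles[i, rules@lhs[[i]]] <- "lhs"
    values[i, rules@rhs[i]] <- v[i]
    roles[i, rules@rhs[i]] <- "rhs"
  }
  list(values = values, roles = roles, metric = metric)
}

#' Write a heatmap matrix as its machine-readable CSV twin
#'
#' Long format: one row per non-absent cell (`rule`, `item`, `role`,
#' `value`) — exactly the numbers plotted.
#'
#' @param hm output of [ruleHeatmap()].
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
writeHeatmapCSV <- function(hm, path) {
  idx <- which(!is.na(hm$values), arr.ind = TRUE)
  df <- data.frame(rule = rownames(hm$values)[idx[, 1L]],
                   item = colnames(hm$values)[idx[, 2L]],
                   role = hm$roles[idx],
                   value = hm$values[idx],
                   stringsAsFactors = FALSE)
  df <- df[order(match(df$rule, rownames(hm$values))), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Plot a rule heatmap
#'
#' Tile plot with a colour scale monotone in the metric (darker = higher);
#' the RHS cell of each rule is marked with a dot.
#'
#' @param hm output of [ruleHeatmap()].
#' @return a ggplot object.
#' @export
plotRuleHeatmap <- function(hm) {
  idx <- which(!is.na(hm$values), arr.ind = TRUE)
  df <- data.frame(rule = factor(rownames(hm$values)[idx[, 1L]],
                                 levels = rev(rownames(hm$values))),
                   item = factor(colnames(hm$values)[idx[, 2L]],
                                 levels = colnames(hm$values)),
                   role = hm$roles[idx], value = hm$values[idx])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item, y = .data$rule,
                                   fill = .data$value)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_point(data = df[df$role == "rhs", , drop = FALSE],
                        size = 0.8) +
    ggplot2::scale_fill_gradient(low = "#deebf7", high = "#08306b",
                                 name = hm$metric) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Association rules:", hm$metric),
                  subtitle = "dot marks the consequent (co-occurrence, not causation)") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Pareto chart of the disease ranking
#'
#' Bars for per-disease patient counts with the cumulative-proportion line
#' and the head threshold.
#'
#' @param pareto a [ParetoResult-class].
#' @return a ggplot object.
#' @export
plotPareto <- function(pareto) {
  r <- pareto@ranked
  r$category <- factor(r$category, levels = r$category)
  scale <- max(r$count)
  ggplot2::ggplot(r, ggplot2::aes(x = .data$category)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative * scale, group = 1),
                       color = "darkorange") +
    ggplot2::geom_hline(yintercept = pareto@threshold * scale,
                        linetype = "dashed") +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / scale,
                                   name = "cumulative proportion")) +
    ggplot2::labs(x = NULL, y = "patients") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Comorbidity-count distribution plot
#'
#' @param dist output of [comorbidityDistribution()].
#' @return a ggplot object.
#' @export
plotComorbidityHistogram <- function(dist) {
  h <- dist$histogram
  h$cumulative <- cumsum(h$proportion)
  scale <- max(h$count)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$n_comorbidities)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cumulative * scale),
                       color = "darkorange") +
    ggplot2::scale_y_continuous(
      sec.axis = ggplot2::sec_axis(~ . / scale,
                                   name = "cumulative proportion")) +
    ggplot2::labs(x = "number of comorbidities", y = "patients") +
    ggplot2::theme_minimal()
}

saveFigure <- function(plot, path, width = 7, height = 5, log = NULL) {
  ok <- tryCatch({
    suppressMessages(ggplot2::ggsave(path, plot, width = width,
                                     height = height, dpi = 120))
    TRUE
  }, error = function(e) {
    if (!is.null(log)) cat("figure skipped (", conditionMessage(e), "): ",
                           path, "\n", sep = "", file = log, append = TRUE)
    FALSE
  })
  invisible(ok)
}

#' Run the full comorbidity-pattern pipeline
#'
#' Chains simulate (or read) -> filter -> transactions -> distribution ->
#' Pareto -> mine -> dedupe -> network -> communities -> render, writing
#' every figure together with its machine-readable twin, a `summary.json`
#' holding all headline numbers, and a `pipeline.log` with stage timings.
#' Two runs with the same inputs produce byte-identical `summary.json`
#' (timings live only in the log).
#'
#' @param config a [CohortConfig-class]; used to simulate a cohort when
#'   `emrPath` is NULL.
#' @param outdir output directory (created if needed).
#' @param emrPath optional path to an existing EMR CSV (skips simulation).
#' @param catalog a [DiseaseCatalog-class].
#' @param minAge eligibility age (default 65).
#' @param minSupport,minConfidence,minLift,maxSize mining thresholds
#'   (defaults: the published 0.01 / 0.5 / 2, itemsets up to size 3).
#' @param paretoThreshold Pareto head threshold (default 0.80).
#' @param networkSeed seed for community detection (default 42).
#' @param minCooccurrence edge threshold (default 1).
#' @param figures render PNG figures (default TRUE; each figure's numbers
#'   are always written as CSV regardless).
#' @return the summary list, invisibly.
#' @export
runPipeline <- function(config = cohortConfig(), outdir,
                        emrPath = NULL, catalog = defaultCatalog(),
                        minAge = 65, minSupport = 0.01,
                        minConfidence = 0.5, minLift = 2, maxSize = 3L,
                        paretoThreshold = 0.80, networkSeed = 42L,
                        minCooccurrence = 1L, figures = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(outdir, "pipeline.log")
  cat("comorbidity pipeline\n", file = logFile)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    el <- proc.time()[["elapsed"]] - t0
    timings[[name]] <<- el
    cat(sprintf("%-14s %8.2fs\n", name, el), file = logFile, append = TRUE)
    out
  }

  records <- stage("ingest", {
    if (is.null(emrPath)) {
      emrPath <- file.path(outdir, "emr.csv")
      writeEMR(generateCohort(config, catalog), emrPath, config)
    }
    readEMR(emrPath)
  })
  filt <- stage("filter", filterCohort(records, catalog, minAge = minAge))
  tdb <- stage("transactions", {
    tdb <- buildTransactions(filt$records, catalog)
    writeBaskets(tdb, file.path(outdir, "transactions.txt"))
    tdb
  })
  dist <- stage("distribution", {
    d <- comorbidityDistribution(tdb)
    utils::write.csv(d$histogram,
                     file.path(outdir, "comorbidity_histogram.csv"),
                     row.names = FALSE)
    utils::write.csv(d$perDisease,
                     file.path(outdir, "per_disease_burden.csv"),
                     row.names = FALSE)
    d
  })
  pareto <- stage("pareto", {
    p <- paretoHead(rankDiseases(tdb), threshold = paretoThreshold)
    writeRankedCSV(p, file.path(outdir, "ranked_diseases.csv"))
    p
  })
  rules <- stage("mine", mineRules(tdb, minSupport = minSupport,
                                   minConfidence = minConfidence,
                                   minLift = minLift, maxSize = maxSize))
  deduped <- stage("dedupe", {
    d <- dedupeByItemset(rules)
    writeRulesCSV(d, file.path(outdir, "rules.csv"),
                  jsonPath = file.path(outdir, "rules.json"))
    d
  })
  net <- partition <- chapters <- NULL
  if (pareto@headSize > 0L) {
    net <- stage("network", {
      nw <- buildNetwork(tdb, nodeSet = headCategories(pareto),
                         minCooccurrence = minCooccurrence,
                         chapters = catalogChapters(catalog))
      utils::write.csv(edgeList(nw), file.path(outdir, "edges.csv"),
                       row.names = FALSE)
      nw
    })
    partition <- stage("communities", detectCommunities(net, seed = networkSeed))
    chapters <- icdChapterPartition(net)
    writeGraphML(net, file.path(outdir, "network.graphml"), partition)
    writeGEXF(net, file.path(outdir, "network.gexf"), partition)
  }
  stage("render", {
    for (mt in c("support", "confidence", "lift")) {
      if (length(deduped) == 0L) {
        cat("no rules above thresholds; heatmaps skipped\n",
            file = logFile, append = TRUE)
        break
      }
      hm <- ruleHeatmap(deduped, mt,
                        columnOrder = pareto@ranked$category)
      writeHeatmapCSV(hm, file.path(outdir,
                                    paste0("heatmap_", mt, ".csv")))
      if (figures)
        saveFigure(plotRuleHeatmap(hm),
                   file.path(outdir, paste0("heatmap_", mt, ".png")),
                   log = logFile)
    }
    if (figures) {
      if (pareto@headSize > 0L)
        saveFigure(plotPareto(pareto), file.path(outdir, "pareto.png"),
                   log = logFile)
      saveFigure(plotComorbidityHistogram(dist),
                 file.path(outdir, "comorbidity_histogram.png"),
                 log = logFile)
    }
    invisible(NULL)
  })
  if (length(deduped) == 0L)
    warning("no association rules passed the thresholds")

  rsum <- summarizeRules(deduped)
  summary <- list(
    parameters = list(min_age = minAge, min_support = minSupport,
                      min_confidence = minConfidence, min_lift = minLift,
                      max_itemset_size = maxSize,
                      pareto_threshold = paretoThreshold,
                      min_cooccurrence = minCooccurrence,
                      network_seed = networkSeed),
    exclusion_report = as.list(filt$report),
    n_patients = nPatients(tdb),
    comorbidity_histogram = dist$histogram,
    pct_without_comorbidity = 100 * dist$histogram$proportion[1L],
    pct_with_comorbidity = 100 * (1 - dist$histogram$proportion[1L]),
    pareto = list(head_size = pareto@headSize,
                  coverage = pareto@coverage,
                  denominator = pareto@denominator),
    rules = list(n_mined = length(rules), n_after_dedup = length(deduped),
                 summary = rsum),
    network = if (!is.null(net)) list(
      n_nodes = igraph::gorder(asGraph(net)),
      n_edges = igraph::gsize(asGraph(net)),
      n_communities = length(unique(partition@assignment)),
      modularity_q = partition@q,
      icd_chapter_q = chapters@q)
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cat("total stages: ", length(timings), "\n", file = logFile, append = TRUE)
  invisible(summary)
}
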
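#' Build the weighted comorbidity co-occurrence network
#'
#' Nodes are morbidity categories; a node's weight is the number of patients
#' carrying the disease and an edge's weight is the number of patients
#' carrying both endpoints (per the convention that an edge connects two
#' diseases observed together in at least one patient). Pairs co-occurring
#' in fewer than `minCooccurrence` patients are omitted. No self-loops.
#'
#' @param tdb a [TransactionDB-class].
#' @param nodeSet labels to include (typically the Pareto head). Default:
#'   every item carried by at least one patient.
#' @param minCooccurrence minimum patients per edge (default 1).
#' @param chapters optional named character vector of ICD-10 chapter tags
#'   per category (default from [defaultCatalog()] where labels match).
#' @return a [ComorbidityNetwork-class].
#' @export
buildNetwork <- function(tdb, nodeSet = NULL, minCooccurrence = 1L,
                         chapters = NULL) {
  if (is.null(nodeSet)) {
    cnt <- itemCounts(tdb)
    nodeSet <- names(cnt)[cnt > 0L]
  }
  if (!length(nodeSet)) stop("nodeSet must be non-empty")
  if (length(bad <- setdiff(nodeSet, itemLabels(tdb))))
    stop("nodeSet labels outside the transaction item universe: ",
         paste(bad, collapse = ", "))
  if (is.null(chapters)) {
    cat0 <- defaultCatalog()
    chapters <- catalogChapters(cat0)
  }
  m <- tdb@incidence[nodeSet, , drop = FALSE]
  co <- as.matrix(Matrix::tcrossprod(m * 1))   # co-occurrence counts
  counts <- diag(co)
  ut <- which(upper.tri(co) & co >= minCooccurrence, arr.ind = TRUE)
  edges <- data.frame(from = nodeSet[ut[, 1L]], to = nodeSet[ut[, 2L]],
                      weight = co[ut], stringsAsFactors = FALSE)
  vertices <- data.frame(name = nodeSet, count = as.numeric(counts),
                         chapter = unname(chapters[nodeSet]),
                         stringsAsFactors = FALSE)
  vertices$chapter[is.na(vertices$chapter)] <- "unknown"
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  methods::new("ComorbidityNetwork", graph = g,
               nPatients = nPatients(tdb),
               minCooccurrence = as.integer(minCooccurrence))
}

asGraph <- function(x) {
  if (methods::is(x, "ComorbidityNetwork")) x@graph else x
}

# dense weighted adjacency in a fixed node order; zero matrix when edgeless
weightMatrix <- function(g, nodes) {
  if (igraph::gsize(g) == 0L)
    return(matrix(0, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes)))
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                             sparse = TRUE))
  W[nodes, nodes, drop = FALSE]
}

#' Edge list of a comorbidity network
#' @param network a [ComorbidityNetwork-class].
#' @return data.frame `from`, `to`, `weight`.
#' @export
edgeList <- function(network) {
  g <- asGraph(network)
  igraph::as_data_frame(g, what = "edges")
}

#' @describeIn nPatients patients behind a network's counts
#' @export
setMethod("nPatients", "ComorbidityNetwork", function(x) x@nPatients)

#' @describeIn ComorbidityNetwork-class compact display
#' @param object a ComorbidityNetwork.
#' @export
setMethod("show", "ComorbidityNetwork", function(object) {
  g <- object@graph
  cat("ComorbidityNetwork:", igraph::gorder(g), "diseases,",
      igraph::gsize(g), "co-occurrence edges (min co-occurrence",
      object@minCooccurrence, "), over", object@nPatients, "patients\n")
})

#' Weighted Newman-Girvan modularity of a partition
#'
#' Direct evaluation of Q = (1/2m) sum_ij (w_ij - g k_i k_j / (2m))
#' d(c_i, c_j), with w the edge weights, k the weighted degrees, m the total
#' edge weight and g the resolution. Independent of any community-detection
#' code, so it can validate a detected partition.
#'
#' @param network a [ComorbidityNetwork-class] or igraph object.
#' @param assignment named vector mapping every node label to a community
#'   id, or a [CommunityPartition-class].
#' @param resolution resolution parameter g (default 1, classic modularity).
#' @return numeric Q in \[-0.5, 1\].
#' @export
modularityQ <- function(network, assignment, resolution = 1) {
  g <- asGraph(network)
  if (methods::is(assignment, "CommunityPartition"))
    assignment <- assignment@assignment
  nodes <- igraph::V(g)$name
  if (length(miss <- setdiff(nodes, names(assignment))))
    stop("assignment missing node(s): ", paste(miss, collapse = ", "))
  W <- weightMatrix(g, nodes)
  m2 <- sum(W)                    # 2m
  if (m2 == 0) return(0)
  k <- rowSums(W)
  B <- W - resolution * outer(k, k) / m2
  comm <- assignment[nodes]
  same <- outer(comm, comm, "==")
  sum(B[same]) / m2
}

#' Detect modularity communities
#'
#' Louvain multilevel optimisation on the weighted graph, restarted over
#' seeded random permutations of the vertex order; the partition with the
#' highest modularity (recomputed with [modularityQ()]) is returned.
#' Deterministic for a fixed seed.
#'
#' @param network a [ComorbidityNetwork-class] or igraph object.
#' @param seed integer RNG seed (default 42).
#' @param resolution resolution parameter (default 1).
#' @param nRestarts restarts with shuffled vertex order (default 10).
#' @return a [CommunityPartition-class].
#' @export
detectCommunities <- function(network, seed = 42L, resolution = 1,
                              nRestarts = 10L) {
  g <- asGraph(network)
  nodes <- igraph::V(g)$name
  if (!length(nodes)) stop("network is empty")
  withLocalSeed(seed, {
    best <- NULL; bestQ <- -Inf
    for (r in seq_len(nRestarts)) {
      perm <- sample(seq_along(nodes))
      gp <- igraph::permute(g, perm)
      cl <- igraph::cluster_louvain(gp, resolution = resolution)
      memb <- igraph::membership(cl)
      assignment <- stats::setNames(as.integer(memb[nodes]), nodes)
      q <- modularityQ(g, assignment, resolution = resolution)
      if (q > bestQ + 1e-12) { bestQ <- q; best <- assignment }
    }
    # renumber communities consecutively in order of first appearance
    best <- stats::setNames(as.integer(factor(best, levels = unique(best))),
                            names(best))
    methods::new("CommunityPartition", assignment = best,
                 q = bestQ, resolution = as.numeric(resolution))
  })
}

#' @describeIn communityAssignment assignment of a partition
#' @export
setMethod("communityAssignment", "CommunityPartition",
          function(x) x@assignment)

#' @describeIn CommunityPartition-class compact display
#' @param object a CommunityPartition.
#' @export
setMethod("show", "CommunityPartition", function(object) {
  cat(sprintf("CommunityPartition: %d communities over %d nodes, Q = %.4f\n",
              length(unique(object@assignment)), length(object@assignment),
              object@q))
})

#' Partition a network by ICD-10 chapter
#'
#' Returns the partition induced by the nodes' ICD-10 chapter tags, with its
#' modularity — useful for comparing data-driven communities against the
#' coding-system taxonomy, without asserting they coincide.
#'
#' @param network a [ComorbidityNetwork-class].
#' @return a [CommunityPartition-class].
#' @export
icdChapterPartition <- function(network) {
  g <- asGraph(network)
  ch <- igraph::V(g)$chapter
  assignment <- stats::setNames(as.integer(factor(ch)), igraph::V(g)$name)
  methods::new("CommunityPartition", assignment = assignment,
               q = modularityQ(g, assignment), resolution = 1)
}

#' Exhaustive modularity maximisation (testing oracle)
#'
#' Enumerates every partition of the node set (via restricted growth
#' strings) and returns the one with maximal modularity. Guarded to small
#' graphs: Bell(10) partitions at most.
#'
#' @param network a [ComorbidityNetwork-class] or igraph object.
#' @param resolution resolution parameter.
#' @param maxNodes guard (default 10).
#' @return list with `assignment` (named integer) and `q`.
#' @export
exhaustiveBestPartition <- function(network, resolution = 1, maxNodes = 10L) {
  g <- asGraph(network)
  nodes <- igraph::V(g)$name
  nn <- length(nodes)
  if (nn > maxNodes) stop("exhaustive search guard: more than ",
                          maxNodes, " nodes")
  W <- weightMatrix(g, nodes)
  m2 <- sum(W)
  if (m2 == 0)
    return(list(assignment = stats::setNames(rep(1L, nn), nodes), q = 0))
  k <- rowSums(W)
  B <- W - resolution * outer(k, k) / m2

  bestQ <- -Inf; best <- NULL
  rgs <- rep(1L, nn)   # restricted growth string enumeration
  repeat {
    q <- 0
    for (c in unique(rgs)) {
      idx <- rgs == c
      q <- q + sum(B[idx, idx])
    }
    q <- q / m2
    if (q > bestQ) { bestQ <- q; best <- rgs }
    # next restricted growth string
    i <- nn
    repeat {
      if (i == 1L) break
      if (rgs[i] <= max(rgs[seq_len(i - 1L)])) { rgs[i] <- rgs[i] + 1L; break }
      rgs[i] <- 1L; i <- i - 1L
    }
    if (i == 1L) break
    if (i < nn) rgs[(i + 1L):nn] <- 1L
  }
  list(assignment = stats::setNames(as.integer(best), nodes), q = bestQ)
}

#' Export a network as GraphML
#'
#' Node attributes `count`, `chapter` and (optionally) `community`; edge
#' attribute `weight`.
#'
#' @param network a [ComorbidityNetwork-class].
#' @param path output file.
#' @param partition optional [CommunityPartition-class] to embed.
#' @return `path`, invisibly.
#' @export
writeGraphML <- function(network, path, partition = NULL) {
  g <- asGraph(network)
  if (!is.null(partition))
    g <- igraph::set_vertex_attr(g, "community",
      value = partition@assignment[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a network as GEXF
#'
#' Minimal GEXF 1.2 writer with node attributes `count`, `chapter`,
#' `community` and weighted edges.
#'
#' @inheritParams writeGraphML
#' @return `path`, invisibly.
#' @export
writeGEXF <- function(network, path, partition = NULL) {
  g <- asGraph(network)
  nodes <- igraph::V(g)$name
  count <- igraph::V(g)$count
  chapter <- igraph::V(g)$chapter
  community <- if (!is.null(partition))
    partition@assignment[nodes] else rep(NA_integer_, length(nodes))
  ed <- igraph::as_data_frame(g, what = "edges")
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '  <graph mode="static" defaultedgetype="undirected">',
    '    <attributes class="node">',
    '      <attribute id="0" title="count" type="double"/>',
    '      <attribute id="1" title="chapter" type="string"/>',
    '      <attribute id="2" title="community" type="integer"/>',
    '    </attributes>',
    '    <nodes>')
  for (i in seq_along(nodes)) {
    lines <- c(lines, sprintf(
      '      <node id="%d" label="%s"><attvalues><attvalue for="0" value="%s"/><attvalue for="1" value="%s"/>%s</attvalues></node>',
      i - 1L, xmlEscape(nodes[i]), format(count[i]),
      xmlEscape(chapter[i]),
      if (is.na(community[i])) ""
      else sprintf('<attvalue for="2" value="%d"/>', community[i])))
  }
  lines <- c(lines, '    </nodes>', '    <edges>')
  if (nrow(ed))
    for (i in seq_len(nrow(ed))) {
      lines <- c(lines, sprintf(
        '      <edge id="%d" source="%d" target="%d" weight="%s"/>',
        i - 1L, match(ed$from[i], nodes) - 1L,
        match(ed$to[i], nodes) - 1L, format(ed$weight[i])))
    }
  lines <- c(lines, '    </edges>', '  </graph>', '</gexf>')
  writeLines(lines, path)
  invisible(path)
}
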
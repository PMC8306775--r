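## Protein-protein interaction network over the core-map proteins:
## construction from an undirected edge list, degree statistics,
## power-law assessment of the degree distribution, betweenness
## centrality, hub ranking and Louvain community detection.

#' Build a weighted undirected PPI network from an edge list
#'
#' Duplicate records of the same unordered pair merge into one edge
#' whose weight is the number of distinct supporting records; supporting
#' PMIDs are unioned. Self-loops are rejected.
#'
#' @param edges A TSV path or data.frame with columns `symbol_a`,
#'   `symbol_b` and optionally `pmid`.
#' @param nodes Optional character vector of node symbols to include
#'   even when isolated (e.g. the full protein list of the map).
#' @return A [PpiNetwork].
#' @examples
#' net <- buildNetwork(data.frame(symbol_a = c("A", "B"),
#'                                symbol_b = c("B", "A")))
#' edgeTable(net)$weight   # 2: the two records collapse into one edge
#' @export
buildNetwork <- function(edges, nodes = NULL) {
  if (is.character(edges) && length(edges) == 1L) {
    df <- .readTsv(edges, c("symbol_a", "symbol_b"), "edge")
    if (!"pmid" %in% names(df)) df$pmid <- character(nrow(df))
  } else {
    df <- as.data.frame(edges, stringsAsFactors = FALSE)
    missing <- setdiff(c("symbol_a", "symbol_b"), names(df))
    if (length(missing) > 0L)
      stop("edge table is missing mandatory column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (!"pmid" %in% names(df)) df$pmid <- character(nrow(df))
  }
  a <- toupper(trimws(as.character(df$symbol_a)))
  b <- toupper(trimws(as.character(df$symbol_b)))
  bad <- which(!nzchar(a) | !nzchar(b))
  if (length(bad) > 0L)
    stop("malformed edge row(s): ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  loops <- which(a == b)
  if (length(loops) > 0L)
    stop("self-loop(s) at row(s): ", paste(head(loops, 5), collapse = ", "),
         call. = FALSE)
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  pmids <- suppressWarnings(as.integer(as.character(df$pmid)))
  edgeRows <- lapply(split(seq_along(key), key), function(idx) {
    data.frame(symbol_a = lo[idx[1]], symbol_b = hi[idx[1]],
               weight = length(idx),
               pmids = I(list(sort(unique(pmids[idx][!is.na(pmids[idx])])))),
               stringsAsFactors = FALSE)
  })
  et <- if (length(edgeRows) > 0L) do.call(rbind, edgeRows) else
    data.frame(symbol_a = character(0), symbol_b = character(0),
               weight = integer(0), pmids = I(list()),
               stringsAsFactors = FALSE)
  et <- et[order(et$symbol_a, et$symbol_b), , drop = FALSE]
  rownames(et) <- NULL
  allNodes <- sort(unique(c(et$symbol_a, et$symbol_b, toupper(nodes))))
  g <- igraph::graph_from_data_frame(
    et[, c("symbol_a", "symbol_b")], directed = FALSE,
    vertices = data.frame(name = allNodes, stringsAsFactors = FALSE))
  if (nrow(et) > 0L) igraph::E(g)$weight <- et$weight
  new("PpiNetwork", graph = g, edges = et)
}

#' Average degree of a network
#'
#' Mean number of neighbors, `2|E| / |V|`.
#'
#' @param network A [PpiNetwork].
#' @return Numeric scalar.
#' @examples
#' fx <- packagedCftrFixture()
#' round(averageDegree(fx$network), 1)   # 4.5
#' @export
averageDegree <- function(network) {
  stopifnot(is(network, "PpiNetwork"))
  n <- igraph::vcount(network@graph)
  if (n == 0L) stop("average degree is undefined on an empty network",
                    call. = FALSE)
  2 * igraph::ecount(network@graph) / n
}

#' Degree histogram
#'
#' Node counts per degree. Satisfies `sum(count) == |V|` and
#' `sum(degree * count) == 2|E|`.
#'
#' @param network A [PpiNetwork].
#' @return data.frame with columns `degree`, `count`, ascending degree.
#' @export
degreeHistogram <- function(network) {
  stopifnot(is(network, "PpiNetwork"))
  deg <- igraph::degree(network@graph)
  tab <- table(deg)
  data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
}

#' Discrete power-law fit of a degree distribution
#'
#' Fits a discrete power law to the positive degrees by maximum
#' likelihood, with the lower cut-off `x_min` chosen by
#' Kolmogorov-Smirnov distance minimization. The distribution is
#' reported as plausibly scale-free when the fit succeeded, the KS
#' distance is below `ksMax`, the fitted exponent does not exceed
#' `alphaMax`, and the fitted tail holds at least `minTail`
#' observations. The exponent bound is essential: on light-tailed
#' (e.g. Poisson) degree data the unconstrained MLE exponent diverges
#' while the KS distance of a far-tail fit can still be small, so a KS
#' threshold alone cannot reject a random graph.
#'
#' @param x A [PpiNetwork], a degree histogram data.frame
#'   (`degree`, `count`), or a vector of degrees.
#' @param ksMax Maximum KS distance (default 0.1).
#' @param alphaMax Maximum plausible exponent (default 5; empirical
#'   scale-free networks lie around 2-3).
#' @param minTail Minimum number of observations at or above `x_min`.
#' @return List of class `"powerLawFit"`: `alpha`, `xmin`, `ks_stat`,
#'   `n_tail`, `plausibly_power_law`, `fit_failed`.
#' @examples
#' set.seed(1)
#' g <- igraph::sample_pa(500, m = 2, directed = FALSE)
#' fitDegreePowerLaw(igraph::degree(g))$plausibly_power_law
#' @export
fitDegreePowerLaw <- function(x, ksMax = 0.1, alphaMax = 5, minTail = 10L) {
  deg <- if (is(x, "PpiNetwork")) igraph::degree(x@graph)
         else if (is.data.frame(x)) rep(x$degree, x$count)
         else as.numeric(x)
  deg <- deg[deg >= 1]
  failure <- structure(list(alpha = NA_real_, xmin = NA_real_,
                            ks_stat = NA_real_, n_tail = NA_integer_,
                            plausibly_power_law = FALSE, fit_failed = TRUE),
                       class = "powerLawFit")
  if (length(deg) < 10L)
    stop("power-law fit requires at least 10 nodes with degree >= 1",
         call. = FALSE)
  if (length(unique(deg)) < 2L) return(failure)
  fit <- tryCatch(
    igraph::fit_power_law(deg, implementation = "plfit"),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$alpha)) return(failure)
  nTail <- sum(deg >= fit$xmin)
  plausible <- is.finite(fit$KS.stat) && fit$KS.stat < ksMax &&
    fit$alpha > 1 && fit$alpha <= alphaMax && nTail >= minTail
  structure(list(alpha = fit$alpha, xmin = fit$xmin,
                 ks_stat = fit$KS.stat, n_tail = nTail,
                 plausibly_power_law = plausible, fit_failed = FALSE),
            class = "powerLawFit")
}

#' @export
print.powerLawFit <- function(x, ...) {
  if (x$fit_failed) {
    cat("Power-law fit: FAILED (degenerate degree distribution)\n")
  } else {
    cat(sprintf(
      "Power-law fit: alpha=%.3f xmin=%g KS=%.4f n_tail=%d plausible=%s\n",
      x$alpha, x$xmin, x$ks_stat, x$n_tail, x$plausibly_power_law))
  }
  invisible(x)
}

#' Betweenness centrality table
#'
#' Exact (Brandes) betweenness for every node, normalized to [0, 1] by
#' `(n-1)(n-2)/2`. Shortest paths are unweighted by default; with
#' `weighted = TRUE` edges are traversed with distance `1/weight`, so
#' heavily supported interactions are shorter.
#'
#' @param network A [PpiNetwork].
#' @param weighted Use `1/weight` edge distances (default `FALSE`).
#' @return data.frame `node`, `degree`, `betweenness`, `rank` (rank 1 =
#'   highest betweenness; ties broken lexicographically by symbol).
#' @export
betweennessTable <- function(network, weighted = FALSE) {
  stopifnot(is(network, "PpiNetwork"))
  g <- network@graph
  n <- igraph::vcount(g)
  w <- if (weighted && igraph::ecount(g) > 0L) 1 / igraph::E(g)$weight else NA
  btw <- igraph::betweenness(g, directed = FALSE, weights = w)
  norm <- if (n > 2L) (n - 1) * (n - 2) / 2 else 1
  btw <- btw / norm
  nodes <- igraph::V(g)$name
  ord <- order(-btw, nodes)
  rank <- integer(n); rank[ord] <- seq_len(n)
  data.frame(node = nodes, degree = as.integer(igraph::degree(g)),
             betweenness = as.numeric(btw), rank = rank,
             stringsAsFactors = FALSE)
}

#' Top hub nodes by degree
#'
#' @param network A [PpiNetwork].
#' @param k Number of hubs (`k <= |V|`).
#' @return data.frame `node`, `degree`, sorted by decreasing degree with
#'   lexicographic tie-break -- a stable, deterministic ranking.
#' @examples
#' fx <- packagedCftrFixture()
#' topHubs(fx$network, 1)$node   # "CFTR"
#' @export
topHubs <- function(network, k) {
  stopifnot(is(network, "PpiNetwork"))
  g <- network@graph
  if (k > igraph::vcount(g))
    stop("k exceeds the number of nodes", call. = FALSE)
  deg <- igraph::degree(g)
  nodes <- igraph::V(g)$name
  ord <- order(-deg, nodes)[seq_len(k)]
  data.frame(node = nodes[ord], degree = as.integer(deg[ord]),
             stringsAsFactors = FALSE)
}

#' Louvain community detection
#'
#' Weighted Louvain modularity optimization; the algorithm's internal
#' randomness is pinned by `seed`, so the partition is reproducible.
#'
#' @param network A [PpiNetwork].
#' @param seed Integer RNG seed.
#' @param resolution Louvain resolution parameter (default 1).
#' @return List of class `"communityPartition"`: `membership` (named
#'   integer), `n_communities`, `modularity`, `seed`.
#' @export
detectCommunities <- function(network, seed = 1L, resolution = 1) {
  stopifnot(is(network, "PpiNetwork"))
  g <- network@graph
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  structure(list(
    membership = setNames(as.integer(memb), igraph::V(g)$name),
    n_communities = length(unique(memb)),
    modularity = igraph::modularity(g, memb,
                                    weights = if (igraph::ecount(g) > 0L)
                                      igraph::E(g)$weight else NULL),
    seed = seed
  ), class = "communityPartition")
}

#' @export
print.communityPartition <- function(x, ...) {
  cat(sprintf("Louvain partition: %d communities, modularity %.4f (seed %d)\n",
              x$n_communities, x$modularity, x$seed))
  invisible(x)
}

#' Per-node metrics table
#'
#' Convenience join of degree, betweenness and community membership,
#' as written by the `topology` pipeline step.
#'
#' @param network A [PpiNetwork].
#' @param seed Seed forwarded to [detectCommunities()].
#' @param weighted Forwarded to [betweennessTable()].
#' @return data.frame `node`, `degree`, `betweenness`, `community`.
#' @export
networkMetricsTable <- function(network, seed = 1L, weighted = FALSE) {
  bt <- betweennessTable(network, weighted = weighted)
  cm <- detectCommunities(network, seed = seed)
  bt$community <- as.integer(cm$membership[bt$node])
  bt[, c("node", "degree", "betweenness", "community")]
}

#' Export a network to GraphML
#'
#' @param network A [PpiNetwork].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeNetworkGraphML <- function(network, path) {
  stopifnot(is(network, "PpiNetwork"))
  igraph::write_graph(network@graph, path, format = "graphml")
  invisible(path)
}
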
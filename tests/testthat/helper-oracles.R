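# Independent oracles used to cross-check the implementation. These are
# deliberately naive and share no code with the package internals.

# Adjacency list from an edge data.frame (symbol_a, symbol_b)
oracleAdjacency <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$symbol_a[i]; b <- edges$symbol_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# BFS distances and shortest-path counts from one source
oracleBfs <- function(adj, source) {
  nodes <- names(adj)
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  sigma <- setNames(rep(0, length(nodes)), nodes)
  dist[source] <- 0; sigma[source] <- 1
  frontier <- source
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# Exhaustive all-pairs betweenness: for every ordered pair (s, t) and
# every intermediate v, count shortest s-t paths through v using the
# path-counting identity sigma_st(v) = sigma_sv * sigma_vt when
# d(s,v) + d(v,t) = d(s,t). Normalized by (n-1)(n-2)/2 (undirected).
oracleBetweenness <- function(edges, nodes) {
  adj <- oracleAdjacency(edges, nodes)
  bfs <- lapply(nodes, function(s) oracleBfs(adj, s))
  names(bfs) <- nodes
  btw <- setNames(rep(0, length(nodes)), nodes)
  for (si in seq_along(nodes)) {
    for (ti in seq_along(nodes)) {
      if (ti <= si) next
      s <- nodes[si]; t <- nodes[ti]
      dst <- bfs[[s]]$dist[t]
      if (is.infinite(dst)) next
      nst <- bfs[[s]]$sigma[t]
      for (v in nodes) {
        if (v == s || v == t) next
        if (bfs[[s]]$dist[v] + bfs[[v]]$dist[t] == dst) {
          btw[v] <- btw[v] + bfs[[s]]$sigma[v] * bfs[[v]]$sigma[t] / nst
        }
      }
    }
  }
  n <- length(nodes)
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
}

# Exhaustive hypergeometric upper tail: enumerate all C(N, n) draws of
# the query size and count those whose overlap with the term reaches
# the observed one.
oracleOraP <- function(universe, termGenes, querySize, overlapObserved) {
  draws <- combn(universe, querySize)
  hits <- apply(draws, 2, function(d)
    length(intersect(d, termGenes)) >= overlapObserved)
  sum(hits) / ncol(draws)
}

# Adjusted Rand index between two labelings
oracleAri <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumIj <- sum(comb2(tab))
  sumI <- sum(comb2(rowSums(tab)))
  sumJ <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sumI * sumJ / comb2(n)
  (sumIj - expected) / ((sumI + sumJ) / 2 - expected)
}

# Log-log least-squares slope of the degree histogram tail: a crude
# power-law exponent estimate, independent of the MLE fit
oracleLogLogSlope <- function(degrees, xmin = 1) {
  tab <- table(degrees[degrees >= xmin])
  k <- as.numeric(names(tab)); n <- as.numeric(tab)
  stats::coef(stats::lm(log(n) ~ log(k)))[2]
}

# Small helpers to write tables for reader tests
writeInteractorTsv <- function(rows, path) {
  header <- paste(c("symbol", "display_name", "species_kind",
                    "localizations", "submaps", "functional_categories",
                    "layer", "hgnc", "uniprot", "chebi", "pubchem_cid"),
                  collapse = "\t")
  writeLines(c(header, rows), path)
}

writeEvidenceTsv <- function(rows, path) {
  header <- paste(c("symbol", "pmid", "evidence_class", "method",
                    "cell_line", "polarized_capable", "human_cells",
                    "research_group"), collapse = "\t")
  writeLines(c(header, rows), path)
}

writeReactionTsv <- function(rows, path) {
  header <- paste(c("id", "rtype", "reactants", "products", "regulators",
                    "compartment", "pmids"), collapse = "\t")
  writeLines(c(header, rows), path)
}

mkEvidenceDf <- function(symbol, pmid, evidence_class = "small_scale_experiment",
                         cell_line = "HEK293", polarized_capable = FALSE,
                         human_cells = TRUE, research_group = "rg1",
                         method = "co-immunoprecipitation") {
  data.frame(symbol = symbol, pmid = as.integer(pmid),
             evidence_class = evidence_class, method = method,
             cell_line = cell_line, polarized_capable = polarized_capable,
             human_cells = human_cells, research_group = research_group,
             stringsAsFactors = FALSE)
}

# The packaged fixture is deterministic and moderately expensive to
# build; construct it once per test run.
packagedFixtureOnce <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- packagedCftrFixture()
    cache
  }
})
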
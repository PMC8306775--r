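test_that("duplicate edge records collapse into weights, (A,B) == (B,A)", {
  net <- buildNetwork(data.frame(symbol_a = c("A", "B"),
                                 symbol_b = c("B", "A"),
                                 pmid = c(1, 2)))
  et <- edgeTable(net)
  expect_equal(nrow(et), 1L)
  expect_equal(et$weight, 2L)
  expect_equal(et$pmids[[1]], c(1L, 2L))
})

test_that("an empty edge file gives an empty network; malformed rows error", {
  f <- tempfile(fileext = ".tsv")
  writeLines("symbol_a\tsymbol_b\tpmid", f)
  net <- buildNetwork(f)
  expect_equal(igraph::vcount(ppiGraph(net)), 0L)
  expect_error(averageDegree(net), "undefined")

  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("symbol_a\tsymbol_b\tpmid", "A\t\t1"), f2)
  expect_error(buildNetwork(f2), "row")
  expect_error(buildNetwork(data.frame(symbol_a = "A", symbol_b = "A")),
               "self-loop")
})

test_that("the fixture network reproduces the printed degree facts", {
  fx <- packagedFixtureOnce()
  net <- fx$network
  g <- ppiGraph(net)
  expect_equal(igraph::vcount(g), 145L)
  expect_equal(igraph::ecount(g), 326L)
  hubs <- topHubs(net, 6)
  expect_equal(hubs$node[1], "CFTR")
  expect_equal(hubs$degree[1], 38L)
  expect_setequal(hubs$node[2:6],
                  c("HSP90AA1", "STUB1", "UBE2I", "NR3C1", "VCP"))
  dh <- degreeHistogram(net)
  expect_equal(dh$count[dh$degree == 1], 30L)
  expect_equal(dh$count[dh$degree == 6], 10L)
})

test_that("average degree is 2E/V", {
  fx <- packagedFixtureOnce()
  expect_equal(averageDegree(fx$network), 2 * 326 / 145)
  tri <- buildNetwork(data.frame(symbol_a = c("A", "B", "C"),
                                 symbol_b = c("B", "C", "A")))
  expect_equal(averageDegree(tri), 2)
  star <- buildNetwork(data.frame(symbol_a = "HUB",
                                  symbol_b = paste0("L", 1:6)))
  expect_equal(averageDegree(star), 12 / 7)
})

test_that("degree histogram satisfies the handshake and counts isolates", {
  star <- buildNetwork(data.frame(symbol_a = "HUB",
                                  symbol_b = paste0("L", 1:5)))
  dh <- degreeHistogram(star)
  expect_equal(dh, data.frame(degree = c(1L, 5L), count = c(5L, 1L)))

  iso <- buildNetwork(data.frame(symbol_a = character(0),
                                 symbol_b = character(0)),
                      nodes = c("A", "B", "C"))
  expect_equal(degreeHistogram(iso), data.frame(degree = 0L, count = 3L))

  # brute-force per-node recount on seeded random graphs
  set.seed(21)
  for (rep in 1:5) {
    g <- igraph::sample_gnp(25, 0.15)
    el <- igraph::as_edgelist(g)
    nodes <- paste0("N", seq_len(25))
    edges <- data.frame(symbol_a = nodes[el[, 1]], symbol_b = nodes[el[, 2]],
                        stringsAsFactors = FALSE)
    net <- buildNetwork(edges, nodes = nodes)
    dh <- degreeHistogram(net)
    expect_equal(sum(dh$count), 25L)
    expect_equal(sum(dh$degree * dh$count), 2L * nrow(edges))
    recount <- table(vapply(nodes, function(v)
      sum(edges$symbol_a == v) + sum(edges$symbol_b == v), integer(1)))
    expect_equal(dh$count, as.integer(recount))
  }
})

test_that("betweenness matches hand-checked graphs", {
  path <- buildNetwork(data.frame(symbol_a = c("A", "B"),
                                  symbol_b = c("B", "C")))
  bt <- betweennessTable(path)
  expect_equal(bt$betweenness[bt$node == "B"], 1)
  expect_equal(bt$betweenness[bt$node %in% c("A", "C")], c(0, 0))

  k4 <- t(combn(c("A", "B", "C", "D"), 2))
  complete <- buildNetwork(data.frame(symbol_a = k4[, 1],
                                      symbol_b = k4[, 2]))
  expect_true(all(betweennessTable(complete)$betweenness == 0))
})

test_that("betweenness equals the exhaustive all-pairs oracle", {
  set.seed(17)
  for (rep in 1:4) {
    n <- sample(10:30, 1)
    g <- igraph::sample_gnp(n, 0.15)
    el <- igraph::as_edgelist(g)
    nodes <- sprintf("N%02d", seq_len(n))
    edges <- data.frame(symbol_a = nodes[el[, 1]],
                        symbol_b = nodes[el[, 2]],
                        stringsAsFactors = FALSE)
    if (nrow(edges) == 0) next
    net <- buildNetwork(edges, nodes = nodes)
    bt <- betweennessTable(net)
    oracle <- oracleBetweenness(edges, nodes)
    expect_equal(setNames(bt$betweenness, bt$node)[nodes],
                 oracle[nodes], tolerance = 1e-10)
  }
})

test_that("topology metrics are invariant under node relabeling", {
  set.seed(33)
  g <- igraph::sample_gnp(20, 0.2)
  el <- igraph::as_edgelist(g)
  nodes <- sprintf("N%02d", 1:20)
  edges <- data.frame(symbol_a = nodes[el[, 1]], symbol_b = nodes[el[, 2]],
                      stringsAsFactors = FALSE)
  net <- buildNetwork(edges, nodes = nodes)
  perm <- setNames(sprintf("M%02d", sample(20)), nodes)
  edges2 <- data.frame(symbol_a = unname(perm[edges$symbol_a]),
                       symbol_b = unname(perm[edges$symbol_b]),
                       stringsAsFactors = FALSE)
  net2 <- buildNetwork(edges2, nodes = unname(perm))
  b1 <- betweennessTable(net); b2 <- betweennessTable(net2)
  m1 <- setNames(b1$betweenness, b1$node)
  m2 <- setNames(b2$betweenness, b2$node)
  expect_equal(unname(m2[unname(perm[names(m1)])]), unname(m1),
               tolerance = 1e-12)
  expect_equal(sort(degreeHistogram(net)$count),
               sort(degreeHistogram(net2)$count))
})

test_that("hub ranking is deterministic with lexicographic ties", {
  star <- buildNetwork(data.frame(symbol_a = "HUB",
                                  symbol_b = paste0("L", 1:5)))
  expect_equal(topHubs(star, 1)$node, "HUB")
  tie <- buildNetwork(data.frame(symbol_a = c("ZZZ", "AAA"),
                                 symbol_b = c("M1", "M2")))
  expect_equal(topHubs(tie, 2)$node, c("AAA", "M1"))
  expect_error(topHubs(tie, 10), "exceeds")
})

test_that("power-law fit separates preferential attachment from Erdos-Renyi", {
  set.seed(4)
  gpa <- igraph::sample_pa(2000, m = 2, directed = FALSE)
  fpa <- fitDegreePowerLaw(igraph::degree(gpa))
  expect_false(fpa$fit_failed)
  expect_gt(fpa$alpha, 2.0)
  expect_lt(fpa$alpha, 3.5)
  expect_true(fpa$plausibly_power_law)
  # cross-check against the log-log least-squares slope oracle
  slope <- oracleLogLogSlope(igraph::degree(gpa))
  expect_gt(abs(slope), 1.2)

  set.seed(4)
  ger <- igraph::sample_gnp(2000, 0.005)
  fer <- fitDegreePowerLaw(igraph::degree(ger))
  expect_false(fer$plausibly_power_law)

  # degenerate histogram: fit failure, not an exception
  flat <- fitDegreePowerLaw(rep(3, 50))
  expect_true(flat$fit_failed)
  expect_false(flat$plausibly_power_law)
  expect_error(fitDegreePowerLaw(c(1, 2, 3)), "at least 10")
})

test_that("Louvain communities are deterministic and recover planted blocks", {
  twoTri <- buildNetwork(data.frame(
    symbol_a = c("A", "B", "C", "X", "Y", "Z"),
    symbol_b = c("B", "C", "A", "Y", "Z", "X")))
  cp <- detectCommunities(twoTri, seed = 1)
  expect_equal(cp$n_communities, 2L)
  expect_equal(length(cp$membership), 6L)

  single <- buildNetwork(data.frame(symbol_a = "A", symbol_b = "B"))
  cs <- detectCommunities(single, seed = 1)
  expect_true(is.finite(cs$modularity))
  expect_length(cs$membership, 2L)

  set.seed(8)
  g <- igraph::sample_sbm(120, pref.matrix = matrix(c(0.25, 0.01,
                                                      0.01, 0.25), 2),
                          block.sizes = c(60, 60))
  el <- igraph::as_edgelist(g)
  nodes <- sprintf("N%03d", 1:120)
  net <- buildNetwork(data.frame(symbol_a = nodes[el[, 1]],
                                 symbol_b = nodes[el[, 2]]),
                      nodes = nodes)
  c1 <- detectCommunities(net, seed = 5)
  c2 <- detectCommunities(net, seed = 5)
  expect_identical(c1$membership, c2$membership)
  planted <- rep(1:2, each = 60)
  expect_gte(oracleAri(c1$membership[nodes], planted), 0.9)
})
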
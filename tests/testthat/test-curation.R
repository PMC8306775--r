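test_that("two distinct-PMID small-scale human experiments are accepted", {
  ev <- mkEvidenceDf("SLC9A3R1", c(101, 102))
  expect_equal(passesInclusionRule(ev), "two_small_scale")
})

test_that("a single experimental reference is rejected", {
  ev <- mkEvidenceDf("SRF", 201)
  expect_equal(passesInclusionRule(ev), "rejected")
  expect_equal(passesInclusionRule(ev[0, ]), "rejected")
})

test_that("reviews count only when from different research groups", {
  sameGroup <- mkEvidenceDf("X", c(1, 2), evidence_class = "review",
                            cell_line = "", human_cells = FALSE)
  expect_equal(passesInclusionRule(sameGroup), "rejected")
  twoGroups <- sameGroup
  twoGroups$research_group <- c("rg1", "rg2")
  expect_equal(passesInclusionRule(twoGroups), "two_reviews")
})

test_that("non-human or high-throughput records never contribute", {
  nonHuman <- mkEvidenceDf("X", c(1, 2), human_cells = FALSE)
  expect_equal(passesInclusionRule(nonHuman), "rejected")
  ht <- mkEvidenceDf("X", c(1, 2), evidence_class = "high_throughput")
  expect_equal(passesInclusionRule(ht), "rejected")
})

test_that("duplicate PMIDs are idempotent for the inclusion rule", {
  ev <- mkEvidenceDf("X", c(5, 5, 5))
  expect_equal(passesInclusionRule(ev), "rejected")
  ok <- mkEvidenceDf("X", c(5, 6))
  expect_equal(passesInclusionRule(rbind(ok, ok, ok)),
               passesInclusionRule(ok))
})

test_that("appending evidence never flips accepted to rejected (monotonicity)", {
  set.seed(99)
  classes <- evidenceClasses()
  for (rep in 1:40) {
    n <- sample(1:6, 1)
    ev <- mkEvidenceDf("X", sample(1:8, n, replace = TRUE),
                       evidence_class = sample(classes, n, replace = TRUE),
                       human_cells = sample(c(TRUE, FALSE), n, replace = TRUE),
                       polarized_capable = sample(c(TRUE, FALSE), n,
                                                  replace = TRUE),
                       research_group = sample(paste0("rg", 1:3), n,
                                               replace = TRUE))
    before <- passesInclusionRule(ev)
    polBefore <- polarityStatus(ev)
    extra <- mkEvidenceDf("X", sample(1:20, 1),
                          evidence_class = sample(classes, 1),
                          human_cells = sample(c(TRUE, FALSE), 1),
                          polarized_capable = sample(c(TRUE, FALSE), 1),
                          research_group = sample(paste0("rg", 1:5), 1))
    after <- passesInclusionRule(rbind(ev, extra))
    if (before != "rejected") expect_false(after == "rejected")
    polAfter <- polarityStatus(rbind(ev, extra))
    if (polBefore == "polarized") expect_equal(polAfter, "polarized")
  }
})

test_that("polarity status distinguishes polarized, non-polarized and no-cell evidence", {
  five <- mkEvidenceDf("X", 1:5, polarized_capable = c(FALSE, FALSE, TRUE,
                                                       FALSE, FALSE))
  expect_equal(polarityStatus(five), "polarized")
  three <- mkEvidenceDf("X", 1:3, polarized_capable = FALSE)
  expect_equal(polarityStatus(three), "non_polarized_only")
  reviews <- mkEvidenceDf("X", 1:2, evidence_class = "review",
                          cell_line = "", human_cells = FALSE)
  expect_equal(polarityStatus(reviews), "no_cell_evidence")
  # brute-force cross-check of the definition on all tiny combinations
  for (pol in c(TRUE, FALSE)) for (cl in c("HEK293", "")) {
    ev <- mkEvidenceDf("X", 1, cell_line = cl, polarized_capable = pol)
    expected <- if (pol) "polarized" else if (nzchar(cl))
      "non_polarized_only" else "no_cell_evidence"
    expect_equal(polarityStatus(ev), expected)
  }
})

test_that("submap summaries compute rounded polarized percentages", {
  it <- data.frame(
    symbol = paste0("P", 1:3), display_name = paste0("P", 1:3),
    species_kind = "protein",
    localizations = I(rep(list("er"), 3)),
    submaps = I(rep(list("folding"), 3)),
    functional_categories = I(rep(list(character(0)), 3)),
    layer = "core", hgnc = "", uniprot = "", chebi = "", pubchem_cid = "",
    stringsAsFactors = FALSE)
  ev <- rbind(mkEvidenceDf("P1", 1:2, polarized_capable = c(TRUE, FALSE)),
              mkEvidenceDf("P2", 3:4, polarized_capable = c(TRUE, FALSE)),
              mkEvidenceDf("P3", 5:6))
  ds <- new("MapDataset", interactors = it, evidence = ev,
            reactions = cftrmapkit:::.emptyReactions(),
            aliases = character(0))
  ss <- summarizeSubmaps(ds)
  expect_equal(nrow(ss), 1L)
  expect_equal(ss$n_interactors, 3L)
  expect_equal(ss$polarized_fraction, 67)   # 100 * 2/3, half-up

  evAll <- rbind(mkEvidenceDf("P1", 1:2, polarized_capable = TRUE),
                 mkEvidenceDf("P2", 3:4, polarized_capable = TRUE),
                 mkEvidenceDf("P3", 5:6, polarized_capable = TRUE))
  dsAll <- new("MapDataset", interactors = it, evidence = evAll,
               reactions = cftrmapkit:::.emptyReactions(),
               aliases = character(0))
  expect_equal(summarizeSubmaps(dsAll)$polarized_fraction, 100)
})

test_that("a submap shaped like the printed Transcription row reproduces 97%", {
  # 28 proteins, 16 RNA/gene elements, 1 small molecule; the 12
  # review-only members carry no cell-line provenance, so the polarized
  # percentage is computed over the 33 cell-evidenced interactors
  spec <- fixtureSpec(
    submaps = list(transcription = list(
      n = 45, polarizedFraction = 32 / 45, reviewOnly = 12,
      kinds = c(protein = 28, rna = 10, gene = 6, simple_molecule = 1))),
    nCoarse = 5, nShared = 0, nReactions = 0,
    graph = list(model = "erdos_renyi", n = 10, p = 0.2),
    annotation = list(nTerms = 1, minSize = 2, maxSize = 3))
  out <- generateDataset(spec, seed = 5, dir = tempfile())
  ss <- summarizeSubmaps(out$dataset)
  expect_equal(ss$n_protein, 28L)
  expect_equal(ss$n_rna + ss$n_gene, 16L)
  expect_equal(ss$n_simple_molecule, 1L)
  expect_equal(ss$polarized_fraction, 97)
})

test_that("submap summaries are invariant under interactor reordering", {
  fx <- packagedFixtureOnce()
  ds <- fx$dataset
  it <- interactors(ds)
  set.seed(7)
  shuffled <- it[sample(nrow(it)), , drop = FALSE]
  rownames(shuffled) <- NULL
  ds2 <- new("MapDataset", interactors = shuffled,
             evidence = evidenceTable(ds), reactions = reactions(ds),
             aliases = aliasMap(ds))
  a <- summarizeSubmaps(ds)
  b <- summarizeSubmaps(ds2)
  a <- a[order(a$submap), ]; b <- b[order(b$submap), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("curation of the packaged fixture accepts all interactors", {
  fx <- packagedFixtureOnce()
  dec <- curateInteractors(fx$dataset)
  expect_equal(nrow(dec), 170L)
  expect_true(all(dec$accepted))
  expect_true(all(dec$basis == "two_small_scale"))
  # accepted=true iff basis != rejected, by construction of the rule
  expect_identical(dec$accepted, dec$basis != "rejected")
})
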
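# minimal two-entity dataset builder for PD map tests
mkTinyDataset <- function(regulators = character(0)) {
  it <- data.frame(
    symbol = c("A", "B", "R"), display_name = c("A", "B", "R"),
    species_kind = "protein",
    localizations = I(rep(list("cytoplasm"), 3)),
    submaps = I(rep(list("interactome"), 3)),
    functional_categories = I(rep(list(character(0)), 3)),
    layer = "core", hgnc = "", uniprot = "", chebi = "", pubchem_cid = "",
    stringsAsFactors = FALSE)
  ev <- rbind(mkEvidenceDf("A", 1:2), mkEvidenceDf("B", 3:4),
              mkEvidenceDf("R", 5:6))
  rx <- data.frame(id = "r1", rtype = "state_transition",
                   reactants = I(list("A")), products = I(list("B")),
                   regulators = I(list(regulators)),
                   compartment = "cytoplasm", pmids = I(list(1L)),
                   stringsAsFactors = FALSE)
  new("MapDataset", interactors = it, evidence = ev, reactions = rx,
      aliases = character(0))
}

test_that("a single reaction yields two entity glyphs, one process, two arcs", {
  m <- buildCoreMap(mkTinyDataset())
  gl <- glyphs(m)
  expect_equal(sum(gl$class == "process"), 1L)
  expect_equal(sum(gl$class == "macromolecule"), 3L)
  expect_equal(nrow(arcs(m)), 2L)
  expect_setequal(arcs(m)$class, c("consumption", "production"))
})

test_that("regulators map onto the PD regulation arc classes", {
  m <- buildCoreMap(mkTinyDataset("R:inhibition"))
  expect_equal(sum(arcs(m)$class == "inhibition"), 1L)
  m2 <- buildCoreMap(mkTinyDataset("R:physical_stimulation"))
  expect_equal(sum(arcs(m2)$class == "stimulation"), 1L)
})

test_that("a reaction in a compartment absent from the layout is an error", {
  ds <- mkTinyDataset()
  expect_error(buildCoreMap(ds, compartmentSet = c("nucleus", "er")),
               "absent from the layout")
})

test_that("the packaged core map has one process glyph per reaction", {
  fx <- packagedFixtureOnce()
  m <- buildCoreMap(fx$dataset)
  expect_equal(sum(glyphs(m)$class == "process"), 156L)
  # multi-compartment entities carry clone markers
  cftrGlyphs <- glyphs(m)[startsWith(glyphs(m)$id, "g_CFTR_"), ]
  expect_equal(nrow(cftrGlyphs), 3L)
  expect_true(all(cftrGlyphs$clone))
})

test_that("color assignment is a pure function of role and polarity", {
  fx <- packagedFixtureOnce()
  m <- buildCoreMap(fx$dataset)
  gl <- glyphs(m)
  expect_equal(unique(gl$style[startsWith(gl$id, "g_CFTR_")]), "sty_cftr")
  dec <- curateInteractors(fx$dataset)
  pol <- dec$symbol[dec$polarity_status == "polarized"][1]
  expect_equal(unique(gl$style[startsWith(gl$id, paste0("g_", pol, "_"))]),
               "sty_polarized")
  nonpol <- dec$symbol[dec$polarity_status == "non_polarized_only"][1]
  expect_equal(unique(gl$style[startsWith(gl$id, paste0("g_", nonpol, "_"))]),
               "sty_non_polarized")
})

test_that("coarse submaps route influences onto the gene node or the transition", {
  it <- data.frame(
    symbol = c(paste0("G", 1:7), paste0("T", 1:10)),
    functional_categories = c(rep("dna_replication", 7),
                              rep("transcription", 10)),
    stringsAsFactors = FALSE)
  m <- buildCoarseSubmap("transcription", it)
  expect_equal(mapDialect(m), "AF")
  expect_equal(interactorGlyphCount(m), 17L)
  ar <- arcs(m)
  interArcs <- ar[!startsWith(ar$source, "cftr_"), ]
  expect_equal(sum(interArcs$target == "cftr_input"), 7L)
  expect_equal(sum(interArcs$target == "cftr_transition"), 10L)
  expect_true(all(interArcs$class == "unknown influence"))
  # one influence arc per non-skipped interactor
  expect_equal(nrow(interArcs), interactorGlyphCount(m))
})

test_that("an empty interactor group yields only the abstraction glyphs", {
  m <- buildCoarseSubmap("activity", data.frame(
    symbol = character(0), functional_categories = character(0)))
  expect_equal(interactorGlyphCount(m), 0L)
  expect_equal(nrow(glyphs(m)), 3L)
})

test_that("interactors with no category in the submap are skipped with a warning", {
  it <- data.frame(symbol = c("A", "B"),
                   functional_categories = c("folding", "transcription"),
                   stringsAsFactors = FALSE)
  expect_warning(m <- buildCoarseSubmap("transcription", it,
                                        categories = "transcription"),
                 "skipped")
  expect_equal(interactorGlyphCount(m), 1L)
})

test_that("grid layout is deterministic and places 4 glyphs on a 2x2 grid", {
  it <- data.frame(symbol = paste0("X", 1:4),
                   functional_categories = "activity",
                   stringsAsFactors = FALSE)
  cfg <- defaultLayoutConfig()
  cfg$columns <- 2L
  base <- buildCoarseSubmap("activity", it)
  m1 <- layoutMap(base, cfg)
  m2 <- layoutMap(base, cfg)
  expect_identical(glyphs(m1), glyphs(m2))
  inter <- glyphs(m1)[!startsWith(glyphs(m1)$id, "cftr_"), ]
  expect_equal(length(unique(inter$x)), 2L)   # 2 columns
  expect_equal(length(unique(inter$y)), 2L)   # 2 rows
})

test_that("layout never overlaps glyph boxes (exhaustive pairwise check)", {
  it <- data.frame(symbol = sprintf("X%02d", 1:30),
                   functional_categories = "activity",
                   stringsAsFactors = FALSE)
  cfg <- defaultLayoutConfig()
  cfg$columns <- 5L
  m <- layoutMap(buildCoarseSubmap("activity", it), cfg)
  gl <- glyphs(m)
  overlap <- function(i, j) {
    !(gl$x[i] + gl$w[i] <= gl$x[j] || gl$x[j] + gl$w[j] <= gl$x[i] ||
      gl$y[i] + gl$h[i] <= gl$y[j] || gl$y[j] + gl$h[j] <= gl$y[i])
  }
  for (i in seq_len(nrow(gl) - 1L))
    for (j in seq(i + 1L, nrow(gl)))
      expect_false(overlap(i, j))
})

test_that("compartments stack bottom-to-top and contain their glyphs", {
  fx <- packagedFixtureOnce()
  m <- layoutMap(buildCoreMap(fx$dataset))
  expect_true(validObject(m))   # validity includes bbox containment
  cp <- compartments(m)
  yOf <- setNames(cp$y, cp$name)
  expect_true(yOf[["nucleus"]] > yOf[["er"]])
  expect_true(yOf[["er"]] > yOf[["golgi"]])
  expect_true(yOf[["golgi"]] > yOf[["cytoplasm"]])
  expect_true(yOf[["cytoplasm"]] > yOf[["plasma_membrane"]])
})

test_that("empty compartments keep a minimum size", {
  it <- data.frame(
    symbol = "A", display_name = "A", species_kind = "protein",
    localizations = I(list("er")), submaps = I(list("x")),
    functional_categories = I(list(character(0))), layer = "core",
    hgnc = "", uniprot = "", chebi = "", pubchem_cid = "",
    stringsAsFactors = FALSE)
  rx <- data.frame(id = "r1", rtype = "transport",
                   reactants = I(list("A@er")), products = I(list("A@er")),
                   regulators = I(list(character(0))),
                   compartment = "nucleus", pmids = I(list(1L)),
                   stringsAsFactors = FALSE)
  ds <- new("MapDataset", interactors = it,
            evidence = mkEvidenceDf("A", 1:2), reactions = rx,
            aliases = character(0))
  m <- layoutMap(buildCoreMap(ds))
  cp <- compartments(m)
  expect_true(all(cp$h > 0))
  cfg <- defaultLayoutConfig()
  minH <- cfg$cellHeight + 2L * cfg$padding
  expect_true(cp$h[cp$name == "nucleus"] >= minH)
})
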
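test_that("reading an interactor table merges rows sharing a symbol", {
  tf <- tempfile(fileext = ".tsv")
  writeInteractorTsv(c(
    "CFTR\tCFTR\tion_channel\ter\tsecretory_pathway\t\tcore\t1884\tP13569\t\t",
    "CFTR\tCFTR\tion_channel\tplasma_membrane\t\t\tcore\t\t\t\t",
    "VCP\tVCP\tprotein\ter\t\t\tcore\t\t\t\t"), tf)
  it <- readInteractorTable(tf)
  expect_equal(nrow(it), 2L)
  expect_setequal(it$localizations[[which(it$symbol == "CFTR")]],
                  c("er", "plasma_membrane"))
  expect_equal(it$uniprot[it$symbol == "CFTR"], "P13569")
})

test_that("an empty table yields an empty interactor list", {
  tf <- tempfile(fileext = ".tsv")
  writeInteractorTsv(character(0), tf)
  expect_equal(nrow(readInteractorTable(tf)), 0L)
})

test_that("missing mandatory columns and conflicting kinds are errors", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("symbol\tdisplay_name", "CFTR\tCFTR"), tf)
  expect_error(readInteractorTable(tf), "species_kind")

  tf2 <- tempfile(fileext = ".tsv")
  writeInteractorTsv(c(
    "CFTR\tCFTR\tion_channel\ter\t\t\tcore\t\t\t\t",
    "CFTR\tCFTR\tprotein\ter\t\t\tcore\t\t\t\t"), tf2)
  expect_error(readInteractorTable(tf2), "conflicting species_kind")
})

test_that("unknown enum values in input are loud errors", {
  tf <- tempfile(fileext = ".tsv")
  writeInteractorTsv("X\tX\tweird_kind\ter\t\t\tcore\t\t\t\t", tf)
  expect_error(readInteractorTable(tf), "species_kind")
  tf2 <- tempfile(fileext = ".tsv")
  writeInteractorTsv("X\tX\tprotein\tmoon\t\t\tcore\t\t\t\t", tf2)
  expect_error(readInteractorTable(tf2), "localization")
})

test_that("evidence loading collapses duplicate PMIDs per interactor", {
  tf <- tempfile(fileext = ".tsv")
  writeEvidenceTsv(c(
    "VCP\t100\tsmall_scale_experiment\tco-ip\tHEK293\t0\t1\trg1",
    "VCP\t100\tsmall_scale_experiment\tco-ip\tHELA\t0\t1\trg1",
    "VCP\t101\treview\t\t\t0\t0\trg2"), tf)
  ev <- readEvidenceTable(tf)
  expect_equal(nrow(ev), 2L)
  expect_equal(sort(ev$pmid), c(100L, 101L))
})

test_that("dataset read-write-read round trip is field-by-field identical", {
  out <- generateDataset(
    fixtureSpec(submaps = list(interactome = list(n = 8,
                  polarizedFraction = 0.25, reviewOnly = 2, kinds = NULL)),
                nCoarse = 10, nShared = 2, nReactions = 4,
                graph = list(model = "erdos_renyi", n = 10, p = 0.2),
                annotation = list(nTerms = 2, minSize = 2, maxSize = 3)),
    seed = 11, dir = tempfile())
  ds <- readMapDataset(out$paths[["interactors"]], out$paths[["evidence"]],
                       out$paths[["reactions"]])
  d <- tempfile(); dir.create(d)
  writeMapDataset(ds, file.path(d, "i.tsv"), file.path(d, "e.tsv"),
                  file.path(d, "r.tsv"))
  ds2 <- readMapDataset(file.path(d, "i.tsv"), file.path(d, "e.tsv"),
                        file.path(d, "r.tsv"))
  expect_equal(interactors(ds), interactors(ds2))
  expect_identical(evidenceTable(ds), evidenceTable(ds2))
  expect_equal(reactions(ds), reactions(ds2))
  expect_identical(aliasMap(ds), aliasMap(ds2))
})

test_that("validateDataset reports unresolved participants and bad identifiers", {
  fx <- packagedFixtureOnce()
  expect_true(validateDataset(fx$dataset, focal = "CFTR")$valid)

  ds <- fx$dataset
  rx <- reactions(ds)
  rx$reactants[[1]] <- c(rx$reactants[[1]], "GHOST1")
  broken <- new("MapDataset", interactors = interactors(ds),
                evidence = evidenceTable(ds), reactions = rx,
                aliases = aliasMap(ds))
  rep <- validateDataset(broken, focal = "CFTR")
  expect_false(rep$valid)
  expect_equal(rep$unresolved_participants$symbol, "GHOST1")

  it <- interactors(ds)
  it$uniprot[it$symbol == "VCP"] <- "???"
  badIds <- new("MapDataset", interactors = it, evidence = evidenceTable(ds),
                reactions = reactions(ds), aliases = aliasMap(ds))
  rep2 <- validateDataset(badIds, focal = "CFTR")
  expect_false(rep2$valid)
  expect_equal(nrow(rep2$malformed_identifiers), 1L)
  expect_equal(rep2$malformed_identifiers$accession, "???")
})

test_that("entity census totals the per-kind counts and handles empty input", {
  empty <- data.frame(symbol = character(0), species_kind = character(0),
                      layer = character(0))
  cen <- entityCensus(empty)
  expect_true(all(cen$counts == 0L))
  expect_equal(cen$total, 0L)

  five <- data.frame(symbol = paste0("P", 1:5), species_kind = "protein",
                     layer = "core")
  cen5 <- entityCensus(five)
  expect_equal(unname(cen5$counts[["protein"]]), 5L)
  expect_equal(cen5$total, 5L)
})

test_that("entity census is permutation-invariant and consistent", {
  fx <- packagedFixtureOnce()
  it <- interactors(fx$dataset)
  set.seed(42)
  shuffled <- it[sample(nrow(it)), , drop = FALSE]
  expect_identical(entityCensus(it), entityCensus(shuffled))
  cen <- entityCensus(it, groupProteins = TRUE)
  expect_equal(sum(cen$counts), cen$total)
})

test_that("identifier syntax checks follow namespace rules", {
  expect_true(validIdentifier("uniprot", "P13569"))
  expect_false(validIdentifier("uniprot", "???"))
  expect_false(validIdentifier("uniprot", "P13"))
  expect_true(validIdentifier("chebi", "CHEBI:15422"))
  expect_false(validIdentifier("pmid", "0"))
})
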
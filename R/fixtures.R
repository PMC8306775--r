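## Synthetic fixtures. Two entry points:
##   * packagedCftrFixture(): a fully deterministic dataset shaped like
##     the published CFTR lifecycle interactome -- it reproduces the
##     printed aggregate counts (entity census, interactor totals, layer
##     overlap, coarse category counts, and the PPI network's degree
##     facts) but is synthetic at the member level: filler symbols are
##     generated, and only the handful of proteins named in the source
##     text (CFTR, HSP90AA1, STUB1, UBE2I, NR3C1, VCP, SLC9A3R1, ANO1)
##     are placed according to their described roles.
##   * generateDataset(): a parameterized generator for controlled test
##     datasets (submap sizes, polarized fractions, layer overlap, graph
##     models, GMT annotations), deterministic given one seed.

.coreSubmapNames <- c("transcription", "er_quality_control",
                      "secretory_pathway", "activity_regulation",
                      "endocytosis_recycling")

.submapCompartment <- c(
  transcription = "nucleus", er_quality_control = "er",
  secretory_pathway = "golgi", activity_regulation = "plasma_membrane",
  endocytosis_recycling = "plasma_membrane",
  interactome = "cytoplasm")

## coarse-layer functional category counts per submap (the study's
## printed high-throughput category table); names are "submap/category"
.coarseCategoryCounts <- c(
  "transcription/dna_replication" = 7L,
  "transcription/transcription" = 10L,
  "rna_processing/rna_processing" = 36L,
  "er_quality_control/folding" = 57L,
  "er_quality_control/erad" = 1L,
  "er_quality_control/folding_and_erad" = 3L,
  "er_quality_control/unspecified" = 653L,
  "secretory_pathway/trafficking" = 22L,
  "activity_regulation/activity" = 38L,
  "activity_regulation/unspecified" = 145L,
  "recycling_degradation/recycling" = 12L,
  "recycling_degradation/degradation" = 32L,
  "cytoskeleton/cytoskeleton" = 62L,
  "immunity/immune_response" = 10L,
  "other/other" = 250L)

.mkSymbols <- function(prefix, n, width = 3) {
  if (n == 0L) return(character(0))
  sprintf(paste0(prefix, "%0", width, "d"), seq_len(n))
}

## evidence rows for one interactor: two independent small-scale human
## experiments; the first uses a polarizable cell line when polarized
.mkEvidence <- function(symbol, polarized, pmid1, pmid2) {
  data.frame(
    symbol = symbol,
    pmid = c(pmid1, pmid2),
    evidence_class = "small_scale_experiment",
    method = c("co-immunoprecipitation", "pull-down assay"),
    cell_line = if (polarized) c("CALU-3", "HEK293") else c("HEK293", "HELA"),
    polarized_capable = c(polarized, FALSE),
    human_cells = TRUE,
    research_group = paste0("rg_", c(pmid1, pmid2)),
    stringsAsFactors = FALSE)
}

#' Packaged CFTR-style fixture dataset
#'
#' Deterministically constructs the synthetic reference dataset used
#' throughout the package's tests and examples. Its aggregates mirror a
#' published CFTR lifecycle interactome: a core layer of 262 molecular
#' entities (149 proteins, 58 complexes, 28 simple molecules, 13 ions,
#' 6 genes, 5 RNAs, 3 degradation pools) with 170 evidenced interactors
#' and 156 reactions across 6 main compartments; per-submap polarized
#' interactor percentages of 97/69/52/82/74; a coarse layer of 1384
#' interactors of which 46 also occur in the core layer (1338 after
#' deduplication, split over the printed functional-category counts);
#' and a PPI network of 145 nodes and 326 edges whose maximum-degree
#' node (38) is CFTR, with 30 degree-1 and 10 degree-6 nodes. Member
#' identities beyond the named hub proteins are synthetic.
#'
#' @return List of class `"cftrFixture"`:
#'   `dataset` (core-layer [MapDataset]), `coarseTable` (pre-dedup
#'   data.frame `symbol`, `submap`, `functional_category`,
#'   `localization`), `coreInteractors` (170 symbols),
#'   `coarseInteractors` (1384 symbols), `network` ([PpiNetwork]),
#'   `networkEdges` (edge data.frame), `isolateProteins` (interactor
#'   proteins absent from the interaction database, reported rather
#'   than silently dropped), `claimedCounts` (the printed coarse
#'   category counts, for [consistencyReport()]).
#' @examples
#' fx <- packagedCftrFixture()
#' entityCensus(fx$dataset, layer = "core")$total
#' computeOverlap(fx$coreInteractors, fx$coarseInteractors)$counts
#' @export
packagedCftrFixture <- function() {
  ## ---- core entities -------------------------------------------------
  cpro <- .mkSymbols("CPRO", 135)
  namedGeneric <- c("HSP90AA1", "STUB1", "UBE2I", "NR3C1", "VCP", "SLC9A3R1")
  proteins <- data.frame(
    symbol = c("CFTR", "ANO1", "ICH01", "RPT01", "RPT02",
               paste0("CFTR-TRUNC", 1:3), namedGeneric, cpro),
    species_kind = c("ion_channel", "ion_channel", "ion_channel",
                     "receptor", "receptor", rep("truncated_protein", 3),
                     rep("protein", 141)),
    stringsAsFactors = FALSE)
  others <- data.frame(
    symbol = c(.mkSymbols("CPLX", 58), .mkSymbols("SM", 28, 2),
               .mkSymbols("ION", 13, 2), "CFTR-GENE",
               .mkSymbols("GEN", 5, 2), "CFTR-MRNA",
               .mkSymbols("RNA", 4, 2),
               "POOL-DEGRADED", "POOL-AA", "POOL-NT"),
    species_kind = c(rep("complex", 58), rep("simple_molecule", 28),
                     rep("ion", 13), rep("gene", 6), rep("rna", 5),
                     rep("degraded_pool", 3)),
    stringsAsFactors = FALSE)
  ent <- rbind(proteins, others)

  ## ---- submap membership and polarity --------------------------------
  ## member lists; within each, the first `nPolarized` are polarized
  sub <- list(
    transcription = list(
      members = c("NR3C1", "UBE2I", cpro[1:22], .mkSymbols("GEN", 5, 2),
                  "RNA01", "RNA02", "RNA03", "RNA04"),
      nPolarized = 32L),
    er_quality_control = list(
      members = c("HSP90AA1", "STUB1", "VCP", cpro[23:46],
                  paste0("SM", sprintf("%02d", 1:4)),
                  cpro[47:58], "SM05", "SM06"),
      nPolarized = 31L),
    secretory_pathway = list(
      members = c("HSP90AA1", cpro[59:71], cpro[72:82], "SM07", "SM08"),
      nPolarized = 14L),
    activity_regulation = list(
      members = c("SLC9A3R1", "ANO1", "RPT01", "RPT02", "ICH01",
                  cpro[83:105], paste0("SM", sprintf("%02d", 9:12)),
                  paste0("ION", sprintf("%02d", 1:4)), cpro[106:113]),
      nPolarized = 36L),
    endocytosis_recycling = list(
      members = c("SLC9A3R1", cpro[114:129], cpro[130:135]),
      nPolarized = 17L))

  submapOf <- lapply(setNames(ent$symbol, ent$symbol), function(s) character(0))
  polarizedOf <- setNames(rep(FALSE, nrow(ent)), ent$symbol)
  for (nm in names(sub)) {
    mem <- sub[[nm]]$members
    for (j in seq_along(mem)) {
      submapOf[[mem[j]]] <- c(submapOf[[mem[j]]], nm)
      if (j <= sub[[nm]]$nPolarized) polarizedOf[mem[j]] <- TRUE
    }
  }
  interactorSyms <- unique(unlist(lapply(sub, `[[`, "members")))

  ## focal species and non-interactor entities
  submapOf[["CFTR-GENE"]] <- "transcription"
  submapOf[["CFTR-MRNA"]] <- "transcription"
  submapOf[["CFTR"]] <- c("secretory_pathway", "activity_regulation",
                          "endocytosis_recycling")
  for (k in 1:3)
    submapOf[[paste0("CFTR-TRUNC", k)]] <- "er_quality_control"
  cplx <- .mkSymbols("CPLX", 58)
  cplxSub <- rep(.coreSubmapNames, times = c(12, 12, 12, 12, 10))
  for (j in seq_along(cplx)) submapOf[[cplx[j]]] <- cplxSub[j]

  locOf <- lapply(setNames(ent$symbol, ent$symbol), function(s) "cytoplasm")
  for (s in names(submapOf)) {
    sm <- submapOf[[s]]
    if (length(sm) > 0L)
      locOf[[s]] <- unique(unname(.submapCompartment[sm]))
  }
  ## complexes take part in the cytoplasmic filler reactions
  for (s in cplx) locOf[[s]] <- "cytoplasm"
  locOf[["CFTR"]] <- c("er", "golgi", "plasma_membrane")
  locOf[["CFTR-GENE"]] <- "nucleus"
  locOf[["CFTR-MRNA"]] <- c("nucleus", "cytoplasm")

  it <- data.frame(
    symbol = ent$symbol,
    display_name = ent$symbol,
    species_kind = ent$species_kind,
    localizations = I(unname(locOf[ent$symbol])),
    submaps = I(unname(submapOf[ent$symbol])),
    functional_categories = I(rep(list(character(0)), nrow(ent))),
    layer = "core",
    hgnc = "", uniprot = "", chebi = "", pubchem_cid = "",
    stringsAsFactors = FALSE)
  ## a few representative identifier annotations
  it$hgnc[it$symbol == "CFTR"] <- "1884"
  it$uniprot[it$symbol == "CFTR"] <- "P13569"
  it$uniprot[it$symbol == "HSP90AA1"] <- "P07900"
  it$chebi[it$symbol == "SM01"] <- "CHEBI:15422"

  ## ---- evidence: two small-scale human experiments per interactor ----
  nPmids <- 221L
  evRows <- vector("list", length(interactorSyms))
  for (i in seq_along(interactorSyms)) {
    p1 <- 90000000L + ((2L * i - 2L) %% nPmids) + 1L
    p2 <- 90000000L + ((2L * i - 1L) %% nPmids) + 1L
    evRows[[i]] <- .mkEvidence(interactorSyms[i],
                               polarizedOf[[interactorSyms[i]]], p1, p2)
  }
  ev <- do.call(rbind, evRows)

  ## ---- reactions -----------------------------------------------------
  sm2 <- .mkSymbols("SM", 28, 2)
  fill <- vector("list", 152)
  for (k in seq_len(152)) {
    a <- cplx[((k - 1L) %% 58L) + 1L]
    b <- cplx[((k + 6L) %% 58L) + 1L]
    s <- sm2[12L + ((k - 1L) %% 16L) + 1L]   # SM13..SM28, cytoplasmic
    reg <- sprintf("%s:%s", cpro[((k - 1L) %% 135L) + 1L],
                   regulationTypes()[((k - 1L) %% 4L) + 1L])
    fill[[k]] <- data.frame(
      id = sprintf("r%03d", k + 4L), rtype = "state_transition",
      reactants = I(list(c(a, s))), products = I(list(b)),
      regulators = I(list(reg)), compartment = "cytoplasm",
      pmids = I(list(90000000L + ((k - 1L) %% nPmids) + 1L)),
      stringsAsFactors = FALSE)
  }
  rx <- rbind(
    data.frame(id = "r001", rtype = "transcription",
               reactants = I(list("CFTR-GENE")),
               products = I(list("CFTR-MRNA")),
               regulators = I(list("NR3C1:catalysis")),
               compartment = "nucleus", pmids = I(list(90000001L)),
               stringsAsFactors = FALSE),
    data.frame(id = "r002", rtype = "translation",
               reactants = I(list("CFTR-MRNA")),
               products = I(list("CFTR@er")),
               regulators = I(list(character(0))),
               compartment = "cytoplasm", pmids = I(list(90000002L)),
               stringsAsFactors = FALSE),
    data.frame(id = "r003", rtype = "transport",
               reactants = I(list("CFTR@er")), products = I(list("CFTR@golgi")),
               regulators = I(list("HSP90AA1:physical_stimulation")),
               compartment = "golgi", pmids = I(list(90000003L)),
               stringsAsFactors = FALSE),
    data.frame(id = "r004", rtype = "transport",
               reactants = I(list("CFTR@golgi")),
               products = I(list("CFTR@plasma_membrane")),
               regulators = I(list("SLC9A3R1:physical_stimulation")),
               compartment = "plasma_membrane", pmids = I(list(90000004L)),
               stringsAsFactors = FALSE),
    do.call(rbind, fill))

  dataset <- new("MapDataset", interactors = it, evidence = ev,
                 reactions = rx, aliases = c(NHRF1 = "SLC9A3R1"))

  ## ---- coarse layer --------------------------------------------------
  shared <- c(namedGeneric, cpro[1:40])                      # 46 symbols
  ht <- .mkSymbols("HT", 1338L, 4)
  cc <- .coarseCategoryCounts
  coarseSub <- sub("/.*$", "", names(cc))
  coarseCat <- sub("^.*/", "", names(cc))
  coarseTable <- data.frame(
    symbol = c(shared, ht),
    submap = c(rep("other", 46L), rep(coarseSub, times = cc)),
    functional_category = c(rep("unspecified", 46L),
                            rep(coarseCat, times = cc)),
    localization = "cytoplasm",
    stringsAsFactors = FALSE)

  ## ---- PPI network ---------------------------------------------------
  ## degree sequence realizing the printed degree facts: CFTR 38 (max),
  ## named hubs next, exactly 10 degree-6 and 30 degree-1 nodes
  degSeq <- c(38L, 22L, 20L, 18L, 16L, 14L, rep(6L, 10), rep(1L, 30),
              rep(2L, 22), rep(3L, 22), rep(4L, 19), rep(5L, 15),
              rep(7L, 10), rep(8L, 5), rep(9L, 2), 10L, 11L, 12L, 12L)
  netNodes <- c("CFTR", namedGeneric[1:5],
                setdiff(c(namedGeneric[6], "ANO1", "RPT01", "RPT02",
                          "ICH01", cpro[1:134]), character(0)))
  stopifnot(length(degSeq) == 145L, length(netNodes) == 145L)
  g <- igraph::realize_degseq(degSeq, method = "smallest")
  el <- igraph::as_edgelist(g, names = FALSE)
  networkEdges <- data.frame(
    symbol_a = netNodes[el[, 1]], symbol_b = netNodes[el[, 2]],
    pmid = 90000000L + ((seq_len(nrow(el)) - 1L) %% nPmids) + 1L,
    stringsAsFactors = FALSE)
  network <- buildNetwork(networkEdges)

  structure(list(
    dataset = dataset,
    coarseTable = coarseTable,
    coreInteractors = interactorSyms,
    coarseInteractors = coarseTable$symbol,
    network = network,
    networkEdges = networkEdges,
    isolateProteins = "CPRO135",
    claimedCounts = cc
  ), class = "cftrFixture")
}

#' @export
print.cftrFixture <- function(x, ...) {
  cat("Synthetic CFTR-style fixture:",
      length(x$coreInteractors), "core /",
      length(x$coarseInteractors), "coarse interactors;",
      nrow(x$dataset@reactions), "reactions;",
      igraph::vcount(x$network@graph), "network nodes\n")
  invisible(x)
}

#' Specification for the synthetic dataset generator
#'
#' Defaults encode the study conditions the packaged fixture mirrors:
#' five core submaps with 33/45/27/44/23 interactors and polarized
#' fractions 32/33, 31/45, 14/27, 36/44 and 17/23 (printed as
#' 97/69/52/82/74 percent), a coarse layer of 1384 with 46 shared
#' symbols split over the printed functional-category counts, a
#' preferential-attachment interaction graph, and a small GMT
#' annotation.
#'
#' @param submaps Named list; each element
#'   `list(n =, polarizedFraction =, reviewOnly = 0, kinds = NULL)`.
#'   `kinds` is an optional named integer vector of species-kind counts
#'   summing to `n` (default: all `protein`); `reviewOnly` members are
#'   supported by two reviews from different research groups instead of
#'   cell-based experiments (they carry no cell-line provenance).
#' @param nCoarse,nShared Coarse-layer size and overlap with the core
#'   layer (`nShared <= min(total core, nCoarse)`).
#' @param coarseCategories Named counts (`"submap/category"`) for the
#'   deduplicated coarse layer; must sum to `nCoarse - nShared`.
#' @param nRejected Extra candidate interactors with insufficient
#'   evidence (one small-scale record only).
#' @param nReactions Filler state-transition reactions.
#' @param graph `list(model =, n =, m =, p =, blockSizes =, pWithin =,
#'   pBetween =)` with model one of `"preferential_attachment"`,
#'   `"erdos_renyi"`, `"planted_partition"`.
#' @param annotation `list(nTerms =, minSize =, maxSize =)` for the GMT
#'   output.
#' @return A list of class `"fixtureSpec"`.
#' @seealso [generateDataset()]
#' @export
fixtureSpec <- function(submaps = NULL, nCoarse = 1384L, nShared = 46L,
                        coarseCategories = NULL, nRejected = 0L,
                        nReactions = 10L, graph = NULL, annotation = NULL) {
  if (is.null(submaps)) {
    ns <- c(33L, 45L, 27L, 44L, 23L)
    pol <- c(32, 31, 14, 36, 17)
    submaps <- setNames(lapply(seq_along(ns), function(i)
      list(n = ns[i], polarizedFraction = pol[i] / ns[i],
           reviewOnly = 0L, kinds = NULL)), .coreSubmapNames)
  }
  ## YAML 1.1 reads a bare `n:` key as the boolean FALSE; accept the
  ## synonyms `size` (submaps) and `nodes` (graph) as well
  fixN <- function(x, synonym) {
    if (is.null(x$n)) {
      alt <- x[[synonym]]
      if (is.null(alt)) alt <- x[["FALSE"]]
      x$n <- alt
      x[[synonym]] <- NULL
      x[["FALSE"]] <- NULL
    }
    x
  }
  for (nm in names(submaps)) {
    submaps[[nm]] <- fixN(submaps[[nm]], "size")
    sm <- submaps[[nm]]
    if (is.null(sm$n)) stop("submap ", nm, " has no size (n)", call. = FALSE)
    if (is.null(sm$reviewOnly)) submaps[[nm]]$reviewOnly <- 0L
    if (is.null(sm$polarizedFraction)) submaps[[nm]]$polarizedFraction <- 0
  }
  if (is.null(coarseCategories)) {
    coarseCategories <-
      if (nCoarse - nShared == sum(.coarseCategoryCounts))
        .coarseCategoryCounts
      else setNames(nCoarse - nShared, "other/other")
  }
  if (is.null(graph))
    graph <- list(model = "preferential_attachment", n = 200L, m = 2L)
  graph <- fixN(graph, "nodes")
  if (is.null(annotation))
    annotation <- list(nTerms = 20L, minSize = 5L, maxSize = 25L)

  spec <- list(submaps = submaps, nCoarse = as.integer(nCoarse),
               nShared = as.integer(nShared),
               coarseCategories = coarseCategories,
               nRejected = as.integer(nRejected),
               nReactions = as.integer(nReactions),
               graph = graph, annotation = annotation)
  class(spec) <- "fixtureSpec"
  .checkFixtureSpec(spec)
  spec
}

.checkFixtureSpec <- function(spec) {
  for (nm in names(spec$submaps)) {
    sm <- spec$submaps[[nm]]
    if (sm$polarizedFraction < 0 || sm$polarizedFraction > 1)
      stop("infeasible spec: polarizedFraction outside [0, 1] in submap ",
           nm, call. = FALSE)
    nPol <- .roundHalfUp(sm$n * sm$polarizedFraction)
    if (nPol > sm$n - sm$reviewOnly)
      stop("infeasible spec: polarized count exceeds the cell-evidenced ",
           "size of submap ", nm, call. = FALSE)
    if (!is.null(sm$kinds) && sum(sm$kinds) != sm$n)
      stop("infeasible spec: kind counts do not sum to n in submap ", nm,
           call. = FALSE)
  }
  nCore <- sum(vapply(spec$submaps, function(s) s$n, numeric(1)))
  if (spec$nShared > min(nCore, spec$nCoarse))
    stop("infeasible spec: overlap exceeds a layer size", call. = FALSE)
  if (sum(spec$coarseCategories) != spec$nCoarse - spec$nShared)
    stop("infeasible spec: coarse category counts must sum to nCoarse - nShared",
         call. = FALSE)
  invisible(TRUE)
}

#' Generate a synthetic dataset bundle
#'
#' Writes a deterministic six-file dataset into `dir`: `interactors.tsv`
#' (core entities), `evidence.tsv`, `reactions.tsv`, `coarse.tsv`
#' (pre-deduplication coarse interactor list), `edges.tsv` (PPI edge
#' list) and `annotations.gmt`. The same spec and seed always produce
#' byte-identical files. Generated evidence satisfies the inclusion
#' rule for all submap members (two small-scale human experiments, or
#' two reviews for `reviewOnly` members) and violates it for the
#' `nRejected` extra candidates; per-submap polarized counts equal
#' `round(n * polarizedFraction)` exactly (half-up).
#'
#' @param spec A [fixtureSpec()].
#' @param seed Integer seed driving all randomness.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the file `paths`, the in-memory
#'   `dataset` ([MapDataset]), `coarseTable`, `coreInteractors`,
#'   `coarseInteractors` and `network`.
#' @examples
#' spec <- fixtureSpec(submaps = list(interactome =
#'   list(n = 10, polarizedFraction = 0.5, reviewOnly = 0, kinds = NULL)),
#'   nCoarse = 20, nShared = 5, nReactions = 2)
#' out <- generateDataset(spec, seed = 1, dir = tempfile())
#' out$dataset
#' @export
generateDataset <- function(spec = fixtureSpec(), seed = 1L, dir) {
  .checkFixtureSpec(spec)
  set.seed(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  ## ---- core interactors ---------------------------------------------
  itRows <- list(); evRows <- list(); symCount <- 0L; pmidNext <- 80000001L
  for (nm in names(spec$submaps)) {
    sm <- spec$submaps[[nm]]
    syms <- sprintf("SYM%04d", symCount + seq_len(sm$n))
    symCount <- symCount + sm$n
    kinds <- if (is.null(sm$kinds)) rep("protein", sm$n)
             else rep(names(sm$kinds), times = sm$kinds)
    comp <- if (nm %in% names(.submapCompartment))
      unname(.submapCompartment[nm]) else "cytoplasm"
    nPol <- .roundHalfUp(sm$n * sm$polarizedFraction)
    ## reviewOnly members are taken from the end of the list so the
    ## first nPol (polarized) members always carry cell evidence
    isReview <- seq_len(sm$n) > sm$n - sm$reviewOnly
    for (j in seq_len(sm$n)) {
      itRows[[length(itRows) + 1L]] <- data.frame(
        symbol = syms[j], display_name = syms[j], species_kind = kinds[j],
        localizations = I(list(comp)), submaps = I(list(nm)),
        functional_categories = I(list(character(0))), layer = "core",
        hgnc = "", uniprot = "", chebi = "", pubchem_cid = "",
        stringsAsFactors = FALSE)
      if (isReview[j]) {
        evRows[[length(evRows) + 1L]] <- data.frame(
          symbol = syms[j], pmid = c(pmidNext, pmidNext + 1L),
          evidence_class = "review", method = "review",
          cell_line = "", polarized_capable = FALSE, human_cells = FALSE,
          research_group = paste0("rg", c(pmidNext, pmidNext + 1L)),
          stringsAsFactors = FALSE)
      } else {
        evRows[[length(evRows) + 1L]] <-
          .mkEvidence(syms[j], j <= nPol, pmidNext, pmidNext + 1L)
      }
      pmidNext <- pmidNext + 2L
    }
  }
  it <- do.call(rbind, itRows)
  coreSyms <- it$symbol
  for (r in seq_len(spec$nRejected)) {
    sym <- sprintf("REJ%04d", r)
    it <- rbind(it, data.frame(
      symbol = sym, display_name = sym, species_kind = "protein",
      localizations = I(list("cytoplasm")), submaps = I(list(character(0))),
      functional_categories = I(list(character(0))), layer = "core",
      hgnc = "", uniprot = "", chebi = "", pubchem_cid = "",
      stringsAsFactors = FALSE))
    evRows[[length(evRows) + 1L]] <- data.frame(
      symbol = sym, pmid = pmidNext, evidence_class = "small_scale_experiment",
      method = "co-immunoprecipitation", cell_line = "HEK293",
      polarized_capable = FALSE, human_cells = TRUE,
      research_group = paste0("rg", pmidNext), stringsAsFactors = FALSE)
    pmidNext <- pmidNext + 1L
  }
  ev <- do.call(rbind, evRows)

  ## ---- reactions: chained state transitions inside the first submap --
  rxRows <- list()
  firstSm <- names(spec$submaps)[1]
  basis <- it$symbol[vapply(it$submaps, function(s) firstSm %in% s,
                            logical(1))]
  rxComp <- if (firstSm %in% names(.submapCompartment))
    unname(.submapCompartment[firstSm]) else "cytoplasm"
  if (length(basis) >= 2L) {
    for (k in seq_len(spec$nReactions)) {
      a <- basis[((k - 1L) %% length(basis)) + 1L]
      b <- basis[(k %% length(basis)) + 1L]
      if (a == b) next
      rxRows[[length(rxRows) + 1L]] <- data.frame(
        id = sprintf("r%03d", k), rtype = "state_transition",
        reactants = I(list(a)), products = I(list(b)),
        regulators = I(list(character(0))), compartment = rxComp,
        pmids = I(list(80000000L + k)), stringsAsFactors = FALSE)
    }
  }
  rx <- if (length(rxRows) > 0L) do.call(rbind, rxRows) else .emptyReactions()

  dataset <- new("MapDataset", interactors = it, evidence = ev,
                 reactions = rx, aliases = character(0))

  ## ---- coarse layer --------------------------------------------------
  shared <- coreSyms[seq_len(spec$nShared)]
  nNew <- spec$nCoarse - spec$nShared
  ht <- .mkSymbols("HT", nNew, 4)
  ccSub <- sub("/.*$", "", names(spec$coarseCategories))
  ccCat <- sub("^.*/", "", names(spec$coarseCategories))
  coarseTable <- data.frame(
    symbol = c(shared, ht),
    submap = c(rep("other", spec$nShared),
               rep(ccSub, times = spec$coarseCategories)),
    functional_category = c(rep("unspecified", spec$nShared),
                            rep(ccCat, times = spec$coarseCategories)),
    localization = "cytoplasm", stringsAsFactors = FALSE)

  ## ---- interaction graph ---------------------------------------------
  gspec <- spec$graph
  g <- switch(gspec$model,
    preferential_attachment =
      igraph::sample_pa(gspec$n, m = gspec$m, directed = FALSE),
    erdos_renyi = igraph::sample_gnp(gspec$n, gspec$p),
    planted_partition = igraph::sample_sbm(
      gspec$n,
      pref.matrix = matrix(c(gspec$pWithin, gspec$pBetween,
                             gspec$pBetween, gspec$pWithin), 2),
      block.sizes = gspec$blockSizes),
    stop("unknown graph model: ", gspec$model, call. = FALSE))
  nodeNames <- .mkSymbols("N", igraph::vcount(g), 4)
  el <- igraph::as_edgelist(g, names = FALSE)
  edgesDf <- data.frame(symbol_a = nodeNames[el[, 1]],
                        symbol_b = nodeNames[el[, 2]],
                        pmid = 80000000L + seq_len(nrow(el)),
                        stringsAsFactors = FALSE)
  edgesDf <- edgesDf[edgesDf$symbol_a != edgesDf$symbol_b, , drop = FALSE]
  network <- buildNetwork(edgesDf, nodes = nodeNames)

  ## ---- annotations ---------------------------------------------------
  ann <- spec$annotation
  pool <- coreSyms
  gmtLines <- character(ann$nTerms)
  for (t in seq_len(ann$nTerms)) {
    size <- sample(seq(ann$minSize, min(ann$maxSize, length(pool))), 1L)
    genes <- sample(pool, size)
    gmtLines[t] <- paste(c(sprintf("T%03d", t), sprintf("term %d", t),
                           genes), collapse = "\t")
  }

  ## ---- write ----------------------------------------------------------
  paths <- c(
    interactors = file.path(dir, "interactors.tsv"),
    evidence = file.path(dir, "evidence.tsv"),
    reactions = file.path(dir, "reactions.tsv"),
    coarse = file.path(dir, "coarse.tsv"),
    edges = file.path(dir, "edges.tsv"),
    annotations = file.path(dir, "annotations.gmt"))
  writeMapDataset(dataset, paths[["interactors"]], paths[["evidence"]],
                  paths[["reactions"]])
  write.table(coarseTable, paths[["coarse"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(edgesDf, paths[["edges"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(gmtLines, paths[["annotations"]])

  invisible(list(paths = paths, dataset = dataset,
                 coarseTable = coarseTable, coreInteractors = coreSyms,
                 coarseInteractors = coarseTable$symbol,
                 network = network))
}
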
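## Tabular I/O for interactor, evidence and reaction tables. Set-valued
## columns are semicolon-separated in the TSV files and list columns in
## memory. Unknown enum values are errors, never silently coerced.

.interactorCols <- c("symbol", "display_name", "species_kind",
                     "localizations", "submaps", "functional_categories",
                     "layer", "hgnc", "uniprot", "chebi", "pubchem_cid")
.evidenceCols <- c("symbol", "pmid", "evidence_class", "method",
                   "cell_line", "polarized_capable", "human_cells",
                   "research_group")
.reactionCols <- c("id", "rtype", "reactants", "products", "regulators",
                   "compartment", "pmids")

.readTsv <- function(path, mandatory, what) {
  if (!file.exists(path)) stop("input file does not exist: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "", colClasses = "character",
                   check.names = FALSE, na.strings = NULL)
  missing <- setdiff(mandatory, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s table %s is missing mandatory column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read an interactor table
#'
#' Reads a tab-separated interactor table (one molecular entity per row)
#' and merges rows that share a gene symbol: set-valued fields are
#' unioned, the first non-empty display name wins, and a conflicting
#' `species_kind` or `layer` for one symbol is a validation error.
#' Symbols are uppercased on load. An optional `aliases` column
#' (semicolon-separated alternative symbols) populates the dataset's
#' alias map.
#'
#' @param path Path to a TSV file with columns `symbol`, `display_name`,
#'   `species_kind`, `localizations`, `submaps`, `functional_categories`,
#'   `layer`, `hgnc`, `uniprot`, `chebi`, `pubchem_cid` (identifier
#'   columns may be empty).
#' @return A data.frame of merged interactors with list columns, plus an
#'   `"aliases"` attribute (named character vector alias -> symbol).
#' @seealso [readMapDataset()] to assemble a full [MapDataset].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(paste(c("symbol", "display_name", "species_kind",
#'     "localizations", "submaps", "functional_categories", "layer",
#'     "hgnc", "uniprot", "chebi", "pubchem_cid"), collapse = "\t"),
#'   "CFTR\tCFTR\tion_channel\ter\t\t\tcore\t1884\tP13569\t\t",
#'   "CFTR\tCFTR\tion_channel\tplasma_membrane\t\t\tcore\t1884\tP13569\t\t"),
#'   tf)
#' it <- readInteractorTable(tf)
#' it$localizations[[1]]   # both compartments merged onto one row
#' @export
readInteractorTable <- function(path) {
  df <- .readTsv(path, setdiff(.interactorCols, c("hgnc", "uniprot",
                                                  "chebi", "pubchem_cid")),
                 "interactor")
  for (cc in c("hgnc", "uniprot", "chebi", "pubchem_cid", "aliases"))
    if (!cc %in% names(df)) df[[cc]] <- character(nrow(df))
  df$symbol <- toupper(trimws(df$symbol))
  if (any(!nzchar(df$symbol)))
    stop("interactor table contains empty symbols", call. = FALSE)
  if (nrow(df) == 0L) {
    out <- data.frame(
      symbol = character(0), display_name = character(0),
      species_kind = character(0), localizations = I(list()),
      submaps = I(list()), functional_categories = I(list()),
      layer = character(0), hgnc = character(0), uniprot = character(0),
      chebi = character(0), pubchem_cid = character(0),
      stringsAsFactors = FALSE)
    attr(out, "aliases") <- character(0)
    return(out)
  }
  .assertEnum(df$species_kind, speciesKinds(), "species_kind")
  .assertEnum(df$layer, c("core", "coarse"), "layer")

  merged <- lapply(split(seq_len(nrow(df)), df$symbol), function(idx) {
    rows <- df[idx, , drop = FALSE]
    if (length(unique(rows$species_kind)) > 1L)
      stop("conflicting species_kind for symbol ", rows$symbol[1],
           call. = FALSE)
    if (length(unique(rows$layer)) > 1L)
      stop("conflicting layer for symbol ", rows$symbol[1], call. = FALSE)
    firstNonEmpty <- function(x) {
      x <- x[nzchar(x)]
      if (length(x) > 0L) x[1] else ""
    }
    data.frame(
      symbol = rows$symbol[1],
      display_name = firstNonEmpty(rows$display_name),
      species_kind = rows$species_kind[1],
      localizations = I(list(unique(unlist(.splitField(rows$localizations))))),
      submaps = I(list(unique(unlist(.splitField(rows$submaps))))),
      functional_categories =
        I(list(unique(unlist(.splitField(rows$functional_categories))))),
      layer = rows$layer[1],
      hgnc = firstNonEmpty(rows$hgnc),
      uniprot = firstNonEmpty(rows$uniprot),
      chebi = firstNonEmpty(rows$chebi),
      pubchem_cid = firstNonEmpty(rows$pubchem_cid),
      aliases = I(list(toupper(unique(unlist(.splitField(rows$aliases)))))),
      stringsAsFactors = FALSE
    )
  })
  ## preserve first-appearance order, not alphabetical split() order
  first <- vapply(split(seq_len(nrow(df)), df$symbol), min, numeric(1))
  out <- do.call(rbind, merged[order(first[names(merged)])])
  rownames(out) <- NULL
  aliases <- character(0)
  for (i in seq_len(nrow(out))) {
    al <- out$aliases[[i]]
    if (length(al) > 0L)
      aliases[al] <- out$symbol[i]
  }
  out$aliases <- NULL
  locs <- unique(unlist(out$localizations))
  .assertEnum(locs, compartmentNames(), "localization")
  attr(out, "aliases") <- aliases
  out
}

#' Read an evidence table
#'
#' One literature support record per row; duplicates by `(symbol, pmid)`
#' are collapsed on load (a PMID is one publication). The 0/1 columns
#' `polarized_capable` and `human_cells` become logicals.
#'
#' @param path TSV with columns `symbol`, `pmid`, `evidence_class`,
#'   `method`, `cell_line`, `polarized_capable`, `human_cells`,
#'   `research_group`.
#' @return data.frame of evidence records.
#' @export
readEvidenceTable <- function(path) {
  df <- .readTsv(path, .evidenceCols, "evidence")
  df$symbol <- toupper(trimws(df$symbol))
  pmid <- suppressWarnings(as.integer(df$pmid))
  if (anyNA(pmid) || any(pmid <= 0L))
    stop("evidence pmid must be a positive integer", call. = FALSE)
  df$pmid <- pmid
  .assertEnum(df$evidence_class, evidenceClasses(), "evidence_class")
  df$polarized_capable <- df$polarized_capable %in% c("1", "TRUE", "true")
  df$human_cells <- df$human_cells %in% c("1", "TRUE", "true")
  df <- df[!duplicated(df[, c("symbol", "pmid")]), , drop = FALSE]
  rownames(df) <- NULL
  df[, .evidenceCols]
}

#' Read a reaction table
#'
#' @param path TSV with columns `id`, `rtype`, `reactants`, `products`
#'   (semicolon-separated symbols, optionally `SYMBOL@compartment` for
#'   transport steps), `regulators` (`SYMBOL:regulation;...`),
#'   `compartment`, `pmids`.
#' @return data.frame of reactions with list columns.
#' @export
readReactionTable <- function(path) {
  df <- .readTsv(path, .reactionCols, "reaction")
  .assertEnum(df$rtype, reactionTypes(), "reaction type")
  .assertEnum(df$compartment, compartmentNames(), "compartment")
  out <- data.frame(
    id = df$id, rtype = df$rtype,
    reactants = I(lapply(.splitField(df$reactants), toupper)),
    products = I(lapply(.splitField(df$products), toupper)),
    regulators = I(lapply(.splitField(df$regulators), toupper)),
    compartment = df$compartment,
    pmids = I(lapply(.splitField(df$pmids), as.integer)),
    stringsAsFactors = FALSE
  )
  regTypes <- unlist(lapply(out$regulators, function(r)
    vapply(strsplit(r, ":", fixed = TRUE),
           function(p) if (length(p) == 2L) tolower(p[2]) else "<malformed>",
           character(1))))
  .assertEnum(regTypes, regulationTypes(), "regulation")
  if (any(lengths(out$reactants) == 0L | lengths(out$products) == 0L))
    stop("reactions must have nonempty reactants and products", call. = FALSE)
  out
}

#' Assemble a MapDataset from its three tables
#'
#' @param interactorPath,evidencePath,reactionPath Paths to the three TSV
#'   files; `evidencePath` and `reactionPath` may be `NULL`.
#' @return A [MapDataset].
#' @export
readMapDataset <- function(interactorPath, evidencePath = NULL,
                           reactionPath = NULL) {
  it <- readInteractorTable(interactorPath)
  aliases <- attr(it, "aliases")
  attr(it, "aliases") <- NULL
  ev <- if (is.null(evidencePath)) .emptyEvidence() else readEvidenceTable(evidencePath)
  rx <- if (is.null(reactionPath)) .emptyReactions() else readReactionTable(reactionPath)
  if (is.null(aliases)) aliases <- character(0)
  new("MapDataset", interactors = it, evidence = ev, reactions = rx,
      aliases = aliases)
}

.emptyEvidence <- function() {
  data.frame(symbol = character(0), pmid = integer(0),
             evidence_class = character(0), method = character(0),
             cell_line = character(0), polarized_capable = logical(0),
             human_cells = logical(0), research_group = character(0),
             stringsAsFactors = FALSE)
}

.emptyReactions <- function() {
  data.frame(id = character(0), rtype = character(0),
             reactants = I(list()), products = I(list()),
             regulators = I(list()), compartment = character(0),
             pmids = I(list()), stringsAsFactors = FALSE)
}

#' Write the tables of a MapDataset back to TSV
#'
#' Inverse of [readMapDataset()]; a read-write-read round trip yields a
#' field-by-field identical dataset.
#'
#' @param dataset A [MapDataset].
#' @param interactorPath,evidencePath,reactionPath Output paths (`NULL`
#'   skips the table).
#' @return Invisibly, the vector of files written.
#' @export
writeMapDataset <- function(dataset, interactorPath, evidencePath = NULL,
                            reactionPath = NULL) {
  stopifnot(is(dataset, "MapDataset"))
  it <- dataset@interactors
  out <- data.frame(
    symbol = it$symbol, display_name = it$display_name,
    species_kind = it$species_kind,
    localizations = .joinField(it$localizations),
    submaps = .joinField(it$submaps),
    functional_categories = .joinField(it$functional_categories),
    layer = it$layer, hgnc = it$hgnc, uniprot = it$uniprot,
    chebi = it$chebi, pubchem_cid = it$pubchem_cid,
    stringsAsFactors = FALSE
  )
  al <- dataset@aliases
  if (length(al) > 0L) {
    out$aliases <- vapply(it$symbol, function(s)
      paste(names(al)[al == s], collapse = ";"), character(1))
  }
  write.table(out, interactorPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  written <- interactorPath
  if (!is.null(evidencePath)) {
    ev <- dataset@evidence
    ev$polarized_capable <- as.integer(ev$polarized_capable)
    ev$human_cells <- as.integer(ev$human_cells)
    write.table(ev, evidencePath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, evidencePath)
  }
  if (!is.null(reactionPath)) {
    rx <- dataset@reactions
    rxOut <- data.frame(
      id = rx$id, rtype = rx$rtype,
      reactants = .joinField(rx$reactants),
      products = .joinField(rx$products),
      regulators = .joinField(rx$regulators),
      compartment = rx$compartment,
      pmids = .joinField(rx$pmids),
      stringsAsFactors = FALSE
    )
    write.table(rxOut, reactionPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
    written <- c(written, reactionPath)
  }
  invisible(written)
}

## strip an optional "@compartment" suffix from a participant token
.participantSymbol <- function(x) sub("@.*$", "", x)

#' Validate a MapDataset
#'
#' Report-based validation: lists reaction participants that do not
#' resolve in the interactor table, malformed database identifiers, and
#' core-layer gene-product entities with no supporting evidence. The
#' dataset is `valid` iff all three lists are empty.
#'
#' The empty-evidence check covers core-layer entities of gene-product
#' kinds (gene, rna, protein, truncated_protein, receptor, ion_channel);
#' small molecules, ions, complexes and degradation pools carry no
#' literature evidence of their own. Entities representing the focal
#' protein itself (symbol equal to `focal` or prefixed `focal-`) are
#' exempt, as they are the subject of the map rather than interactors.
#'
#' @param dataset A [MapDataset].
#' @param focal Optional focal symbol (e.g. `"CFTR"`).
#' @return A list of class `"mapValidation"` with elements
#'   `unresolved_participants` (data.frame `reaction`, `symbol`),
#'   `malformed_identifiers` (data.frame `symbol`, `namespace`,
#'   `accession`), `empty_evidence_core` (character), `valid` (logical).
#' @examples
#' fx <- packagedCftrFixture()
#' validateDataset(fx$dataset, focal = "CFTR")$valid
#' @export
validateDataset <- function(dataset, focal = NULL) {
  stopifnot(is(dataset, "MapDataset"))
  it <- dataset@interactors
  known <- it$symbol

  unresolved <- data.frame(reaction = character(0), symbol = character(0),
                           stringsAsFactors = FALSE)
  rx <- dataset@reactions
  for (i in seq_len(nrow(rx))) {
    syms <- .participantSymbol(c(rx$reactants[[i]], rx$products[[i]],
                                 sub(":.*$", "", rx$regulators[[i]])))
    bad <- setdiff(unique(syms), known)
    if (length(bad) > 0L)
      unresolved <- rbind(unresolved,
                          data.frame(reaction = rx$id[i], symbol = bad,
                                     stringsAsFactors = FALSE))
  }

  malformed <- data.frame(symbol = character(0), namespace = character(0),
                          accession = character(0), stringsAsFactors = FALSE)
  for (ns in c("hgnc", "uniprot", "chebi", "pubchem_cid")) {
    acc <- it[[ns]]
    has <- !is.na(acc) & nzchar(acc)
    bad <- has & !validIdentifier(ns, acc)
    if (any(bad))
      malformed <- rbind(malformed,
                         data.frame(symbol = it$symbol[bad], namespace = ns,
                                    accession = acc[bad],
                                    stringsAsFactors = FALSE))
  }

  geneProduct <- c("gene", "rna", "protein", "truncated_protein",
                   "receptor", "ion_channel")
  needEv <- it$symbol[it$layer == "core" & it$species_kind %in% geneProduct]
  if (!is.null(focal)) {
    needEv <- needEv[needEv != toupper(focal) &
                       !startsWith(needEv, paste0(toupper(focal), "-"))]
  }
  emptyEv <- setdiff(needEv, unique(dataset@evidence$symbol))

  structure(list(
    unresolved_participants = unresolved,
    malformed_identifiers = malformed,
    empty_evidence_core = emptyEv,
    valid = nrow(unresolved) == 0L && nrow(malformed) == 0L &&
      length(emptyEv) == 0L
  ), class = "mapValidation")
}

#' @export
print.mapValidation <- function(x, ...) {
  cat("Map dataset validation:", if (x$valid) "VALID" else "INVALID", "\n")
  cat("  unresolved reaction participants:",
      nrow(x$unresolved_participants), "\n")
  cat("  malformed identifiers:", nrow(x$malformed_identifiers), "\n")
  cat("  core entities without evidence:",
      length(x$empty_evidence_core), "\n")
  invisible(x)
}

#' Census of molecular entities by species kind
#'
#' Counts the entities of a layer by species kind. Every registered kind
#' appears in the result (zero counts included) and the reported total
#' equals the sum of the per-kind counts. With `groupProteins = TRUE`
#' the protein subtypes (generic, truncated, receptor, ion channel) are
#' pooled into one `protein` count, the grouping conventionally used
#' when reporting map content.
#'
#' @param dataset A [MapDataset] or an interactor data.frame.
#' @param layer `"core"`, `"coarse"` or `NULL` for all layers.
#' @param groupProteins Pool the four protein kinds (default `FALSE`).
#' @return A list with `counts` (named integer) and `total`.
#' @examples
#' fx <- packagedCftrFixture()
#' entityCensus(fx$dataset, layer = "core", groupProteins = TRUE)$counts
#' entityCensus(fx$dataset, layer = "core")$total   # 262
#' @export
entityCensus <- function(dataset, layer = NULL, groupProteins = FALSE) {
  it <- if (is(dataset, "MapDataset")) dataset@interactors else dataset
  if (!is.null(layer) && nrow(it) > 0L) it <- it[it$layer == layer, , drop = FALSE]
  kind <- it$species_kind
  lev <- speciesKinds()
  if (groupProteins) {
    proteinKinds <- c("protein", "truncated_protein", "receptor",
                      "ion_channel")
    kind[kind %in% proteinKinds] <- "protein"
    lev <- c("protein", setdiff(lev, proteinKinds))
  }
  counts <- table(factor(kind, levels = lev))
  counts <- setNames(as.integer(counts), names(counts))
  list(counts = counts, total = sum(counts))
}

#' Symbols of the interactors of a layer
#'
#' An interactor is an entity that influences the focal protein and is
#' supported by literature evidence: entities with at least one evidence
#' record, excluding the focal protein's own species (symbol equal to
#' `focal` or prefixed `focal-`). Coarse-layer entities need no evidence
#' records (their provenance is the high-throughput source) and count as
#' interactors unless they are focal species.
#'
#' @param dataset A [MapDataset].
#' @param layer `"core"` or `"coarse"`.
#' @param focal Focal symbol, default `"CFTR"`.
#' @return Character vector of interactor symbols.
#' @export
interactorSymbols <- function(dataset, layer = "core", focal = "CFTR") {
  stopifnot(is(dataset, "MapDataset"))
  it <- dataset@interactors
  it <- it[it$layer == layer, , drop = FALSE]
  syms <- it$symbol
  focal <- toupper(focal)
  syms <- syms[syms != focal & !startsWith(syms, paste0(focal, "-"))]
  if (identical(layer, "core"))
    syms <- intersect(syms, unique(dataset@evidence$symbol))
  syms
}
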
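#' MapDataset: interactors, evidence and reactions of one map layer set
#'
#' Container for a curated interaction dataset. The `interactors` slot
#' holds one row per molecular entity (keyed by uppercased gene symbol)
#' with set-valued fields (localizations, submaps, functional categories)
#' stored as list columns; `evidence` holds one literature support record
#' per row, joined to interactors by symbol; `reactions` holds one
#' reaction per row with list-column participants. `aliases` maps
#' alternative symbols to canonical ones (explicit table, never fuzzy
#' matching).
#'
#' @slot interactors data.frame with columns `symbol`, `display_name`,
#'   `species_kind`, `localizations` (list), `submaps` (list),
#'   `functional_categories` (list), `layer`, `hgnc`, `uniprot`, `chebi`,
#'   `pubchem_cid`.
#' @slot evidence data.frame with columns `symbol`, `pmid`,
#'   `evidence_class`, `method`, `cell_line`, `polarized_capable`,
#'   `human_cells`, `research_group`.
#' @slot reactions data.frame with columns `id`, `rtype`, `reactants`
#'   (list of `"SYMBOL"` or `"SYMBOL@compartment"`), `products` (list),
#'   `regulators` (list of `"SYMBOL:regulation"`), `compartment`,
#'   `pmids` (list of integer).
#' @slot aliases named character vector, alias -> canonical symbol.
#'
#' @seealso [readInteractorTable()], [validateDataset()], [entityCensus()]
#' @export
setClass("MapDataset", representation(
  interactors = "data.frame",
  evidence    = "data.frame",
  reactions   = "data.frame",
  aliases     = "character"
))

setValidity("MapDataset", function(object) {
  msgs <- character(0)
  it <- object@interactors
  if (nrow(it) > 0L) {
    if (any(!nzchar(it$symbol)) || anyNA(it$symbol))
      msgs <- c(msgs, "interactor symbols must be nonempty")
    if (any(it$symbol != toupper(it$symbol)))
      msgs <- c(msgs, "interactor symbols must be uppercased")
    if (anyDuplicated(it$symbol))
      msgs <- c(msgs, "interactor symbols must be unique within the table")
    bad <- setdiff(unique(it$species_kind), speciesKinds())
    if (length(bad) > 0L)
      msgs <- c(msgs, paste("unknown species_kind:", paste(bad, collapse = ", ")))
    bad <- setdiff(unique(it$layer), c("core", "coarse"))
    if (length(bad) > 0L)
      msgs <- c(msgs, paste("unknown layer:", paste(bad, collapse = ", ")))
    locs <- unique(unlist(it$localizations))
    bad <- setdiff(locs, compartmentNames())
    if (length(bad) > 0L)
      msgs <- c(msgs, paste("unknown localization:", paste(bad, collapse = ", ")))
  }
  ev <- object@evidence
  if (nrow(ev) > 0L) {
    if (any(!is.na(ev$pmid) & ev$pmid <= 0L))
      msgs <- c(msgs, "evidence pmid must be a positive integer")
    bad <- setdiff(unique(ev$evidence_class), evidenceClasses())
    if (length(bad) > 0L)
      msgs <- c(msgs, paste("unknown evidence_class:", paste(bad, collapse = ", ")))
  }
  rx <- object@reactions
  if (nrow(rx) > 0L) {
    bad <- setdiff(unique(rx$rtype), reactionTypes())
    if (length(bad) > 0L)
      msgs <- c(msgs, paste("unknown reaction type:", paste(bad, collapse = ", ")))
    if (anyDuplicated(rx$id))
      msgs <- c(msgs, "reaction ids must be unique")
    empt <- lengths(rx$reactants) == 0L | lengths(rx$products) == 0L
    if (any(empt))
      msgs <- c(msgs, "reactions must have nonempty reactants and products")
  }
  if (length(msgs) == 0L) TRUE else msgs
})

#' SbgnMap: a compartmentalized SBGN glyph/arc graph
#'
#' In-memory representation of one SBGN map in either the Process
#' Description (`"PD"`) or Activity Flow (`"AF"`) dialect. Bounding boxes
#' are abstract layout units (integers after [layoutMap()]); a width of
#' zero means "not yet laid out".
#'
#' @slot dialect `"PD"` or `"AF"`.
#' @slot glyphs data.frame: `id`, `class`, `label`, `compartment` (id of
#'   the containing compartment or `NA`), `x`, `y`, `w`, `h`, `style`
#'   (style id or `NA`), `clone` (logical clone marker).
#' @slot arcs data.frame: `id`, `class`, `source`, `target`.
#' @slot compartments data.frame: `id`, `name`, `x`, `y`, `w`, `h`.
#' @slot styles data.frame: `id`, `fill`, `stroke`.
#' @seealso [buildCoreMap()], [buildCoarseSubmap()], [layoutMap()],
#'   [writeSbgnMl()]
#' @export
setClass("SbgnMap", representation(
  dialect      = "character",
  glyphs       = "data.frame",
  arcs         = "data.frame",
  compartments = "data.frame",
  styles       = "data.frame"
))

## glyph classes legal in each dialect (entity-pool, process and
## activity nodes; arcs listed separately)
.pdGlyphClasses <- c("macromolecule", "nucleic acid feature",
                     "simple chemical", "complex", "source and sink",
                     "unspecified entity", "process", "phenotype")
.afGlyphClasses <- c("biological activity", "phenotype")
.pdArcClasses <- c("consumption", "production", "catalysis", "inhibition",
                   "stimulation", "modulation", "necessary stimulation")
.afArcClasses <- c("positive influence", "negative influence",
                   "unknown influence", "necessary stimulation")

setValidity("SbgnMap", function(object) {
  msgs <- character(0)
  if (length(object@dialect) != 1L || !object@dialect %in% c("PD", "AF"))
    msgs <- c(msgs, "dialect must be \"PD\" or \"AF\"")
  gl <- object@glyphs; ar <- object@arcs; cp <- object@compartments
  if (nrow(gl) > 0L) {
    legal <- if (identical(object@dialect, "AF")) .afGlyphClasses else .pdGlyphClasses
    bad <- setdiff(unique(gl$class), legal)
    if (length(bad) > 0L)
      msgs <- c(msgs, paste("glyph class not legal for dialect:",
                            paste(bad, collapse = ", ")))
    if (anyDuplicated(gl$id)) msgs <- c(msgs, "glyph ids must be unique")
    badRef <- setdiff(gl$compartment[!is.na(gl$compartment)], cp$id)
    if (length(badRef) > 0L)
      msgs <- c(msgs, paste("glyph references missing compartment:",
                            paste(badRef, collapse = ", ")))
    badSty <- setdiff(gl$style[!is.na(gl$style)], object@styles$id)
    if (length(badSty) > 0L)
      msgs <- c(msgs, paste("glyph references missing style:",
                            paste(badSty, collapse = ", ")))
    ## laid-out glyphs must sit fully inside their compartment
    laid <- which(gl$w > 0 & !is.na(gl$compartment))
    for (i in laid) {
      j <- match(gl$compartment[i], cp$id)
      if (!is.na(j) && cp$w[j] > 0) {
        inside <- gl$x[i] >= cp$x[j] && gl$y[i] >= cp$y[j] &&
          gl$x[i] + gl$w[i] <= cp$x[j] + cp$w[j] &&
          gl$y[i] + gl$h[i] <= cp$y[j] + cp$h[j]
        if (!inside) {
          msgs <- c(msgs, sprintf("glyph %s lies outside compartment %s",
                                  gl$id[i], gl$compartment[i]))
          break
        }
      }
    }
  }
  if (nrow(ar) > 0L) {
    legal <- if (identical(object@dialect, "AF")) .afArcClasses else .pdArcClasses
    bad <- setdiff(unique(ar$class), legal)
    if (length(bad) > 0L)
      msgs <- c(msgs, paste("arc class not legal for dialect:",
                            paste(bad, collapse = ", ")))
    ends <- unique(c(ar$source, ar$target))
    bad <- setdiff(ends, gl$id)
    if (length(bad) > 0L)
      msgs <- c(msgs, paste("arc endpoint references missing glyph:",
                            paste(bad, collapse = ", ")))
  }
  if (length(msgs) == 0L) TRUE else msgs
})

#' PpiNetwork: weighted undirected protein-protein interaction graph
#'
#' Nodes are gene symbols; each edge carries a weight equal to the number
#' of distinct supporting interaction records and the union of their
#' supporting PMIDs. Self-loops are disallowed and (A,B) is identical to
#' (B,A).
#'
#' @slot graph an [igraph::igraph] object (undirected, simple, edge
#'   attribute `weight`).
#' @slot edges data.frame: `symbol_a`, `symbol_b` (with
#'   `symbol_a < symbol_b`), `weight`, `pmids` (list of integer).
#' @seealso [buildNetwork()], [averageDegree()], [betweennessTable()]
#' @export
setClass("PpiNetwork", representation(
  graph = "ANY",
  edges = "data.frame"
))

setValidity("PpiNetwork", function(object) {
  msgs <- character(0)
  if (!igraph::is_igraph(object@graph))
    return("graph slot must hold an igraph object")
  g <- object@graph
  if (igraph::is_directed(g)) msgs <- c(msgs, "graph must be undirected")
  if (igraph::any_loop(g)) msgs <- c(msgs, "self-loops are not allowed")
  if (igraph::any_multiple(g))
    msgs <- c(msgs, "duplicate edges must be collapsed into weights")
  if (igraph::ecount(g) != nrow(object@edges))
    msgs <- c(msgs, "edge table and graph disagree on edge count")
  if (length(msgs) == 0L) TRUE else msgs
})
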
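#' Accessors for MapDataset, SbgnMap and PpiNetwork
#'
#' Slot access for the package's S4 containers. `interactors()`,
#' `evidenceTable()` and `reactions()` return the component data.frames
#' of a [MapDataset]; `glyphs()`, `arcs()`, `compartments()`, `styles()`
#' and `mapDialect()` expose an [SbgnMap]; `ppiGraph()` and `edgeTable()`
#' expose a [PpiNetwork].
#'
#' @param x The object.
#' @return The corresponding data.frame (or character/igraph object).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("interactors", function(x) standardGeneric("interactors"))
#' @rdname accessors
#' @export
setGeneric("evidenceTable", function(x) standardGeneric("evidenceTable"))
#' @rdname accessors
#' @export
setGeneric("reactions", function(x) standardGeneric("reactions"))
#' @rdname accessors
#' @export
setGeneric("aliasMap", function(x) standardGeneric("aliasMap"))
#' @rdname accessors
#' @export
setGeneric("glyphs", function(x) standardGeneric("glyphs"))
#' @rdname accessors
#' @export
setGeneric("arcs", function(x) standardGeneric("arcs"))
#' @rdname accessors
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))
#' @rdname accessors
#' @export
setGeneric("styles", function(x) standardGeneric("styles"))
#' @rdname accessors
#' @export
setGeneric("mapDialect", function(x) standardGeneric("mapDialect"))
#' @rdname accessors
#' @export
setGeneric("ppiGraph", function(x) standardGeneric("ppiGraph"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setMethod("interactors", "MapDataset", function(x) x@interactors)
#' @rdname accessors
#' @export
setMethod("evidenceTable", "MapDataset", function(x) x@evidence)
#' @rdname accessors
#' @export
setMethod("reactions", "MapDataset", function(x) x@reactions)
#' @rdname accessors
#' @export
setMethod("aliasMap", "MapDataset", function(x) x@aliases)
#' @rdname accessors
#' @export
setMethod("glyphs", "SbgnMap", function(x) x@glyphs)
#' @rdname accessors
#' @export
setMethod("arcs", "SbgnMap", function(x) x@arcs)
#' @rdname accessors
#' @export
setMethod("compartments", "SbgnMap", function(x) x@compartments)
#' @rdname accessors
#' @export
setMethod("styles", "SbgnMap", function(x) x@styles)
#' @rdname accessors
#' @export
setMethod("mapDialect", "SbgnMap", function(x) x@dialect)
#' @rdname accessors
#' @export
setMethod("ppiGraph", "PpiNetwork", function(x) x@graph)
#' @rdname accessors
#' @export
setMethod("edgeTable", "PpiNetwork", function(x) x@edges)

setMethod("show", "MapDataset", function(object) {
  it <- object@interactors
  cat("MapDataset with", nrow(it), "entities (",
      sum(it$layer == "core"), "core /", sum(it$layer == "coarse"),
      "coarse ),", nrow(object@evidence), "evidence records,",
      nrow(object@reactions), "reactions\n")
  if (nrow(it) > 0L) {
    tab <- table(factor(it$species_kind, levels = speciesKinds()))
    tab <- tab[tab > 0L]
    cat("  kinds:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
})

setMethod("show", "SbgnMap", function(object) {
  cat("SbgnMap <", object@dialect, "> with ", nrow(object@glyphs),
      " glyphs, ", nrow(object@arcs), " arcs, ",
      nrow(object@compartments), " compartments\n", sep = "")
})

setMethod("show", "PpiNetwork", function(object) {
  cat("PpiNetwork with", igraph::vcount(object@graph), "nodes and",
      igraph::ecount(object@graph), "edges\n")
})
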
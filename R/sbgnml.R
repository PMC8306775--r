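## SBGN-ML 0.2 serialization. The writer emits a canonical, byte-stable
## document (fixed element order, integer-preserving number formatting)
## so identical maps serialize identically; style (fill color)
## assignments travel in a renderInformation extension with per-style
## glyph id lists.

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

.fmtNum <- function(x) {
  format(x, trim = TRUE, scientific = FALSE, drop0trailing = TRUE)
}

.sbgnLanguage <- c(PD = "process description", AF = "activity flow")

#' Write a map to SBGN-ML
#'
#' Serializes an [SbgnMap] to an SBGN-ML 0.2 XML file. The output is
#' deterministic: the same map always produces a byte-identical file.
#' A write-read round trip through [readSbgnMl()] preserves glyphs,
#' arcs, compartments, labels, classes, bounding boxes, clone markers
#' and style assignments exactly.
#'
#' @param map An [SbgnMap].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @examples
#' it <- data.frame(symbol = "A", functional_categories = "transcription")
#' m <- layoutMap(buildCoarseSubmap("Transcription", it))
#' f <- tempfile(fileext = ".sbgn")
#' writeSbgnMl(m, f)
#' identical(glyphs(readSbgnMl(f)), glyphs(m))
#' @export
writeSbgnMl <- function(map, path) {
  stopifnot(is(map, "SbgnMap"))
  validObject(map)
  gl <- map@glyphs; ar <- map@arcs; cp <- map@compartments; st <- map@styles
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbgn xmlns="http://sbgn.org/libsbgn/0.2">',
    sprintf('  <map language="%s">', .sbgnLanguage[[map@dialect]])
  )
  if (nrow(st) > 0L) {
    lines <- c(lines,
      "    <extension>",
      paste0('      <renderInformation xmlns="http://www.sbml.org/sbml/',
             'level3/version1/render/version1" id="renderInformation">'),
      "        <listOfStyles>")
    for (i in seq_len(nrow(st))) {
      ids <- gl$id[!is.na(gl$style) & gl$style == st$id[i]]
      lines <- c(lines, sprintf(
        '          <style id="%s" fill="%s" stroke="%s" idList="%s"/>',
        st$id[i], st$fill[i], st$stroke[i], paste(ids, collapse = " ")))
    }
    lines <- c(lines,
      "        </listOfStyles>",
      "      </renderInformation>",
      "    </extension>")
  }
  for (i in seq_len(nrow(cp))) {
    lines <- c(lines, sprintf(
      paste0('    <glyph id="%s" class="compartment">',
             '<label text="%s"/>',
             '<bbox x="%s" y="%s" w="%s" h="%s"/></glyph>'),
      cp$id[i], .xmlEscape(cp$name[i]),
      .fmtNum(cp$x[i]), .fmtNum(cp$y[i]),
      .fmtNum(cp$w[i]), .fmtNum(cp$h[i])))
  }
  for (i in seq_len(nrow(gl))) {
    compAttr <- if (is.na(gl$compartment[i])) ""
                else sprintf(' compartmentRef="%s"', gl$compartment[i])
    inner <- sprintf('<label text="%s"/><bbox x="%s" y="%s" w="%s" h="%s"/>',
                     .xmlEscape(gl$label[i]),
                     .fmtNum(gl$x[i]), .fmtNum(gl$y[i]),
                     .fmtNum(gl$w[i]), .fmtNum(gl$h[i]))
    if (isTRUE(gl$clone[i])) inner <- paste0(inner, "<clone/>")
    lines <- c(lines, sprintf('    <glyph id="%s" class="%s"%s>%s</glyph>',
                              gl$id[i], gl$class[i], compAttr, inner))
  }
  centerOf <- function(gid) {
    j <- match(gid, gl$id)
    c(gl$x[j] + gl$w[j] %/% 2L, gl$y[j] + gl$h[j] %/% 2L)
  }
  for (i in seq_len(nrow(ar))) {
    s <- centerOf(ar$source[i]); e <- centerOf(ar$target[i])
    lines <- c(lines, sprintf(
      paste0('    <arc id="%s" class="%s" source="%s" target="%s">',
             '<start x="%s" y="%s"/><end x="%s" y="%s"/></arc>'),
      ar$id[i], ar$class[i], ar$source[i], ar$target[i],
      .fmtNum(s[1]), .fmtNum(s[2]), .fmtNum(e[1]), .fmtNum(e[2])))
  }
  lines <- c(lines, "  </map>", "</sbgn>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a map from SBGN-ML
#'
#' Parses an SBGN-ML 0.2 file into an [SbgnMap]. Malformed XML raises
#' the parser error (with the offending line); a structurally invalid
#' map -- e.g. an arc referencing a missing glyph id -- is a parse
#' error as well.
#'
#' @param path SBGN-ML file.
#' @return An [SbgnMap].
#' @export
readSbgnMl <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "sbgn")
    stop("parse error: not an SBGN-ML document (root element is <",
         xml2::xml_name(doc), ">)", call. = FALSE)
  mapNode <- xml2::xml_find_first(doc, "./map")
  if (inherits(mapNode, "xml_missing"))
    stop("parse error: SBGN-ML document has no <map> element", call. = FALSE)
  lang <- xml2::xml_attr(mapNode, "language")
  dialect <- names(.sbgnLanguage)[match(lang, .sbgnLanguage)]
  if (is.na(dialect))
    stop("parse error: unsupported SBGN language: ", lang, call. = FALSE)

  styleNodes <- xml2::xml_find_all(mapNode, ".//listOfStyles/style")
  st <- data.frame(
    id = xml2::xml_attr(styleNodes, "id"),
    fill = xml2::xml_attr(styleNodes, "fill"),
    stroke = xml2::xml_attr(styleNodes, "stroke"),
    stringsAsFactors = FALSE)
  styleOfGlyph <- character(0)
  for (i in seq_along(styleNodes)) {
    ids <- strsplit(xml2::xml_attr(styleNodes[[i]], "idList"), " ",
                    fixed = TRUE)[[1]]
    ids <- ids[nzchar(ids)]
    styleOfGlyph[ids] <- st$id[i]
  }

  glyphNodes <- xml2::xml_find_all(mapNode, "./glyph")
  cls <- xml2::xml_attr(glyphNodes, "class")
  parseBbox <- function(node) {
    bb <- xml2::xml_find_first(node, "./bbox")
    as.numeric(c(xml2::xml_attr(bb, "x"), xml2::xml_attr(bb, "y"),
                 xml2::xml_attr(bb, "w"), xml2::xml_attr(bb, "h")))
  }
  compRows <- list(); glyphRows <- list()
  for (i in seq_along(glyphNodes)) {
    node <- glyphNodes[[i]]
    gid <- xml2::xml_attr(node, "id")
    lab <- xml2::xml_attr(xml2::xml_find_first(node, "./label"), "text")
    if (is.na(lab)) lab <- ""
    bb <- parseBbox(node)
    if (cls[i] == "compartment") {
      compRows[[length(compRows) + 1L]] <- data.frame(
        id = gid, name = lab, x = bb[1], y = bb[2], w = bb[3], h = bb[4],
        stringsAsFactors = FALSE)
    } else {
      sty <- styleOfGlyph[gid]
      glyphRows[[length(glyphRows) + 1L]] <- data.frame(
        id = gid, class = cls[i], label = lab,
        compartment = xml2::xml_attr(node, "compartmentRef"),
        x = bb[1], y = bb[2], w = bb[3], h = bb[4],
        style = if (is.null(sty) || is.na(sty)) NA_character_ else unname(sty),
        clone = !inherits(xml2::xml_find_first(node, "./clone"),
                          "xml_missing"),
        stringsAsFactors = FALSE)
    }
  }
  cp <- if (length(compRows) > 0L) do.call(rbind, compRows) else
    data.frame(id = character(0), name = character(0), x = numeric(0),
               y = numeric(0), w = numeric(0), h = numeric(0),
               stringsAsFactors = FALSE)
  gl <- if (length(glyphRows) > 0L) do.call(rbind, glyphRows) else .emptyGlyphs()

  arcNodes <- xml2::xml_find_all(mapNode, "./arc")
  ar <- data.frame(
    id = xml2::xml_attr(arcNodes, "id"),
    class = xml2::xml_attr(arcNodes, "class"),
    source = xml2::xml_attr(arcNodes, "source"),
    target = xml2::xml_attr(arcNodes, "target"),
    stringsAsFactors = FALSE)
  if (nrow(ar) == 0L) ar <- .emptyArcs()

  badEnds <- setdiff(unique(c(ar$source, ar$target)), gl$id)
  if (length(badEnds) > 0L)
    stop("parse error: arc references missing glyph id(s): ",
         paste(badEnds, collapse = ", "), call. = FALSE)

  new("SbgnMap", dialect = dialect, glyphs = gl, arcs = ar,
      compartments = cp, styles = st)
}
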
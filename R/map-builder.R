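## SBGN map generation: a mechanistic Process Description core map built
## from entities + reactions, and Activity Flow coarse submaps that
## abstract one lifecycle step into a central state transition.

#' Default fill-color scheme for generated maps
#'
#' Concrete colors for the color roles used throughout the maps: the
#' focal protein in blue, interactors seen in polarized cell lines in
#' green, non-polarized-only interactors in yellow,
#' degradation-associated interactors in red, recycling-associated ones
#' in orange, compartments in grey.
#'
#' @return Named character vector of hex RGB colors over the roles
#'   `cftr`, `polarized`, `non_polarized`, `degradation`, `recycling`,
#'   `compartment`, `unspecified`.
#' @export
defaultColorScheme <- function() {
  c(cftr = "#2B6CB0", polarized = "#8FBF8F", non_polarized = "#F2E394",
    degradation = "#E57373", recycling = "#F2C879",
    compartment = "#D9D9D9", unspecified = "#EDEDED")
}

.checkColorScheme <- function(colorScheme) {
  roles <- names(defaultColorScheme())
  missing <- setdiff(roles, names(colorScheme))
  if (length(missing) > 0L)
    stop("color scheme is missing role(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- !grepl("^#[0-9A-Fa-f]{6}$", colorScheme[roles])
  if (any(bad))
    stop("invalid hex color for role(s): ",
         paste(roles[bad], collapse = ", "), call. = FALSE)
  colorScheme[roles]
}

.styleFrame <- function(colorScheme) {
  colorScheme <- .checkColorScheme(colorScheme)
  data.frame(id = paste0("sty_", names(colorScheme)),
             fill = unname(colorScheme), stroke = "#000000",
             stringsAsFactors = FALSE)
}

.speciesGlyphClass <- c(
  gene = "nucleic acid feature", rna = "nucleic acid feature",
  protein = "macromolecule", truncated_protein = "macromolecule",
  receptor = "macromolecule", ion_channel = "macromolecule",
  complex = "complex", simple_molecule = "simple chemical",
  ion = "simple chemical", degraded_pool = "source and sink"
)

.regulationArcClass <- c(
  catalysis = "catalysis", inhibition = "inhibition",
  physical_stimulation = "stimulation", modulation = "modulation"
)

.emptyGlyphs <- function() {
  data.frame(id = character(0), class = character(0), label = character(0),
             compartment = character(0), x = numeric(0), y = numeric(0),
             w = numeric(0), h = numeric(0), style = character(0),
             clone = logical(0), stringsAsFactors = FALSE)
}

.emptyArcs <- function() {
  data.frame(id = character(0), class = character(0), source = character(0),
             target = character(0), stringsAsFactors = FALSE)
}

.isFocal <- function(symbol, focal) {
  symbol == focal | startsWith(symbol, paste0(focal, "-"))
}

#' Build the Process Description core map
#'
#' Generates one SBGN PD map from the core layer of a dataset: one
#' entity glyph per (entity, localization) occurrence (entities present
#' in several compartments receive clone markers), one process glyph per
#' reaction with consumption/production arcs, and regulation arcs with
#' catalysis/inhibition/stimulation/modulation classes. Fill colors
#' encode the focal protein (blue) and each interactor's polarity
#' provenance (green/yellow).
#'
#' Reaction participants resolve to the glyph of the participating
#' symbol in the reaction's compartment (a `SYMBOL@compartment` token
#' overrides, e.g. for transport steps); regulators attach from the
#' regulator's first glyph. The map is returned without layout
#' coordinates; pass it through [layoutMap()] before serializing.
#'
#' @param dataset A validated [MapDataset].
#' @param compartmentSet Compartments available in the layout; a
#'   reaction referencing a compartment outside this set is an error.
#' @param colorScheme See [defaultColorScheme()].
#' @param focal Focal symbol (default `"CFTR"`); entities named `focal`
#'   or `focal-*` are colored as the focal protein.
#' @return An [SbgnMap] with dialect `"PD"`.
#' @examples
#' fx <- packagedCftrFixture()
#' m <- buildCoreMap(fx$dataset)
#' sum(glyphs(m)$class == "process")   # one process glyph per reaction
#' @export
buildCoreMap <- function(dataset, compartmentSet = compartmentNames(),
                         colorScheme = defaultColorScheme(),
                         focal = "CFTR") {
  stopifnot(is(dataset, "MapDataset"))
  it <- dataset@interactors
  it <- it[it$layer == "core", , drop = FALSE]
  rx <- dataset@reactions
  focal <- toupper(focal)

  bad <- setdiff(unique(rx$compartment), compartmentSet)
  if (length(bad) > 0L)
    stop("reaction(s) reference compartment(s) absent from the layout: ",
         paste(bad, collapse = ", "), call. = FALSE)

  usedComps <- unique(c(unlist(it$localizations), rx$compartment))
  usedComps <- usedComps[nzchar(usedComps)]
  bad <- setdiff(usedComps, compartmentSet)
  if (length(bad) > 0L)
    stop("entities are localized to compartment(s) absent from the layout: ",
         paste(bad, collapse = ", "), call. = FALSE)
  compDf <- data.frame(id = paste0("comp_", usedComps), name = usedComps,
                       x = 0, y = 0, w = 0, h = 0, stringsAsFactors = FALSE)

  decisions <- curateInteractors(dataset)
  polStatus <- setNames(decisions$polarity_status, decisions$symbol)
  roleOf <- function(symbol) {
    if (.isFocal(symbol, focal)) return("cftr")
    st <- polStatus[symbol]
    if (is.na(st)) return("unspecified")
    switch(st, polarized = "polarized",
           non_polarized_only = "non_polarized", "unspecified")
  }

  glyphRows <- vector("list", nrow(it))
  for (i in seq_len(nrow(it))) {
    locs <- it$localizations[[i]]
    if (length(locs) == 0L) locs <- "cytoplasm"
    sym <- it$symbol[i]
    glyphRows[[i]] <- data.frame(
      id = paste0("g_", sym, "_", locs),
      class = unname(.speciesGlyphClass[it$species_kind[i]]),
      label = if (nzchar(it$display_name[i])) it$display_name[i] else sym,
      compartment = paste0("comp_", locs),
      x = 0, y = 0, w = 0, h = 0,
      style = paste0("sty_", roleOf(sym)),
      clone = length(locs) > 1L,
      stringsAsFactors = FALSE
    )
  }
  gl <- if (length(glyphRows) > 0L) do.call(rbind, glyphRows) else .emptyGlyphs()

  ## symbol -> glyph in the entity's first listed compartment
  ## (regulation arcs attach there; participants resolve by compartment)
  firstGlyphOf <- setNames(character(0), character(0))
  for (i in seq_len(nrow(it))) {
    locs <- it$localizations[[i]]
    if (length(locs) == 0L) locs <- "cytoplasm"
    firstGlyphOf[it$symbol[i]] <- paste0("g_", it$symbol[i], "_", locs[1])
  }

  resolveGlyph <- function(token, defaultComp, reactionId) {
    sym <- .participantSymbol(token)
    comp <- if (grepl("@", token, fixed = TRUE)) sub("^.*@", "", token)
            else defaultComp
    gid <- paste0("g_", sym, "_", comp)
    if (!gid %in% gl$id)
      stop(sprintf("reaction %s: participant %s has no glyph in compartment %s",
                   reactionId, sym, comp), call. = FALSE)
    gid
  }

  arcRows <- list()
  procRows <- list()
  aN <- 0L
  for (i in seq_len(nrow(rx))) {
    pid <- paste0("p_", rx$id[i])
    procRows[[i]] <- data.frame(
      id = pid, class = "process", label = "",
      compartment = paste0("comp_", rx$compartment[i]),
      x = 0, y = 0, w = 0, h = 0, style = NA_character_, clone = FALSE,
      stringsAsFactors = FALSE
    )
    for (tok in rx$reactants[[i]]) {
      aN <- aN + 1L
      arcRows[[aN]] <- data.frame(
        id = paste0("a", aN), class = "consumption",
        source = resolveGlyph(tok, rx$compartment[i], rx$id[i]),
        target = pid, stringsAsFactors = FALSE)
    }
    for (tok in rx$products[[i]]) {
      aN <- aN + 1L
      arcRows[[aN]] <- data.frame(
        id = paste0("a", aN), class = "production", source = pid,
        target = resolveGlyph(tok, rx$compartment[i], rx$id[i]),
        stringsAsFactors = FALSE)
    }
    for (reg in rx$regulators[[i]]) {
      parts <- strsplit(reg, ":", fixed = TRUE)[[1]]
      regSym <- parts[1]
      regType <- tolower(parts[2])
      src <- firstGlyphOf[regSym]
      if (is.na(src))
        stop(sprintf("reaction %s: regulator %s not in interactor table",
                     rx$id[i], regSym), call. = FALSE)
      aN <- aN + 1L
      arcRows[[aN]] <- data.frame(
        id = paste0("a", aN), class = unname(.regulationArcClass[regType]),
        source = unname(src), target = pid, stringsAsFactors = FALSE)
    }
  }
  gl <- rbind(gl, if (length(procRows) > 0L) do.call(rbind, procRows))
  ar <- if (aN > 0L) do.call(rbind, arcRows) else .emptyArcs()
  rownames(gl) <- NULL
  styDf <- .styleFrame(colorScheme)
  styDf <- styDf[styDf$id %in% c(gl$style, "sty_compartment"), , drop = FALSE]
  rownames(styDf) <- NULL
  new("SbgnMap", dialect = "PD", glyphs = gl, arcs = ar,
      compartments = compDf, styles = styDf)
}

#' Build one Activity Flow coarse submap
#'
#' Abstracts one lifecycle step into a central state transition: a focal
#' input activity, a transition activity named after the step, and a
#' focal output activity, connected by positive influences. Every
#' interactor becomes a biological-activity glyph with one influence arc
#' routed either onto the input (gene) node -- for the gene-directed
#' functional categories -- or onto the transition. Interactors carrying
#' no category of this submap are skipped with a warning.
#'
#' @param name Submap name (used as the transition label).
#' @param interactorTable data.frame with columns `symbol` and
#'   `functional_categories` (list column or semicolon-separated
#'   character).
#' @param categories Functional categories belonging to this submap;
#'   `NULL` accepts every category present.
#' @param geneCategories Categories routed onto the input/gene node
#'   (default: DNA replication, DNA repair, chromatin).
#' @param abstraction Labels of the three abstraction glyphs (`input`,
#'   `transition` -- defaults to `name` -- and `output`).
#' @param influenceClass Arc class for interactor influences
#'   (`"unknown influence"` by default; the nature of these
#'   high-throughput interactions is unreported).
#' @param colorScheme See [defaultColorScheme()]; interactor colors are
#'   a pure function of the functional category (degradation-type
#'   categories red, recycling orange, unspecified/other yellow, all
#'   specific categories green).
#' @return An [SbgnMap] with dialect `"AF"`. The abstraction glyphs have
#'   ids `cftr_input`, `cftr_transition`, `cftr_output`; see
#'   [interactorGlyphCount()].
#' @examples
#' it <- data.frame(symbol = c("A", "B"),
#'                  functional_categories = c("dna_replication",
#'                                            "transcription"))
#' m <- buildCoarseSubmap("Transcription", it)
#' interactorGlyphCount(m)   # 2
#' @export
buildCoarseSubmap <- function(name, interactorTable, categories = NULL,
                              geneCategories = c("dna_replication",
                                                 "dna_repair", "chromatin"),
                              abstraction = list(input = "CFTR gene",
                                                 transition = NULL,
                                                 output = "CFTR"),
                              influenceClass = c("unknown influence",
                                                 "positive influence"),
                              colorScheme = defaultColorScheme()) {
  influenceClass <- match.arg(influenceClass)
  if (is.null(abstraction$transition)) abstraction$transition <- name
  cats <- interactorTable$functional_categories
  if (!is.list(cats)) cats <- .splitField(as.character(cats))
  syms <- toupper(interactorTable$symbol)

  gl <- data.frame(
    id = c("cftr_input", "cftr_transition", "cftr_output"),
    class = "biological activity",
    label = c(abstraction$input, abstraction$transition, abstraction$output),
    compartment = NA_character_, x = 0, y = 0, w = 0, h = 0,
    style = "sty_cftr", clone = FALSE, stringsAsFactors = FALSE)
  ar <- data.frame(
    id = c("a_backbone1", "a_backbone2"), class = "positive influence",
    source = c("cftr_input", "cftr_transition"),
    target = c("cftr_transition", "cftr_output"), stringsAsFactors = FALSE)

  catRole <- function(cc) {
    if (any(cc %in% c("degradation", "erad", "folding_and_erad")))
      "degradation"
    else if (any(cc %in% "recycling")) "recycling"
    else if (length(setdiff(cc, c("unspecified", "other"))) > 0L) "polarized"
    else "non_polarized"
  }

  skipped <- character(0)
  aN <- 0L
  for (i in seq_along(syms)) {
    cc <- cats[[i]]
    if (!is.null(categories)) cc <- intersect(cc, categories)
    if (length(cc) == 0L) {
      skipped <- c(skipped, syms[i])
      next
    }
    gid <- paste0("g_", syms[i])
    gl <- rbind(gl, data.frame(
      id = gid, class = "biological activity", label = syms[i],
      compartment = NA_character_, x = 0, y = 0, w = 0, h = 0,
      style = paste0("sty_", catRole(cc)), clone = FALSE,
      stringsAsFactors = FALSE))
    aN <- aN + 1L
    target <- if (any(cc %in% geneCategories)) "cftr_input" else "cftr_transition"
    ar <- rbind(ar, data.frame(
      id = paste0("a", aN), class = influenceClass, source = gid,
      target = target, stringsAsFactors = FALSE))
  }
  if (length(skipped) > 0L)
    warning(sprintf("submap %s: skipped %d interactor(s) with no category in this submap: %s",
                    name, length(skipped),
                    paste(head(skipped, 5), collapse = ", ")), call. = FALSE)
  rownames(gl) <- NULL
  rownames(ar) <- NULL
  styDf <- .styleFrame(colorScheme)
  styDf <- styDf[styDf$id %in% gl$style, , drop = FALSE]
  rownames(styDf) <- NULL
  new("SbgnMap", dialect = "AF", glyphs = gl, arcs = ar,
      compartments = data.frame(id = character(0), name = character(0),
                                x = numeric(0), y = numeric(0),
                                w = numeric(0), h = numeric(0),
                                stringsAsFactors = FALSE),
      styles = styDf)
}

#' Count interactor glyphs of a coarse submap
#'
#' Number of activity glyphs excluding the three focal-abstraction
#' glyphs (`cftr_input`, `cftr_transition`, `cftr_output`).
#'
#' @param map An [SbgnMap] built by [buildCoarseSubmap()].
#' @return Integer count.
#' @export
interactorGlyphCount <- function(map) {
  stopifnot(is(map, "SbgnMap"))
  gl <- map@glyphs
  sum(!gl$id %in% c("cftr_input", "cftr_transition", "cftr_output"))
}

#' Default layout configuration
#'
#' Parameters of the deterministic grid layout (abstract integer layout
#' units). Compartments are stacked bottom-to-top in `compartmentOrder`
#' (nucleus at the bottom, extracellular space on top, mirroring the
#' focal protein's journey); glyphs are gridded inside their
#' compartment with `columns` per row.
#'
#' @return A named list of layout parameters.
#' @export
defaultLayoutConfig <- function() {
  list(
    columns = 5L,
    cellWidth = 130L, cellHeight = 70L,
    glyphWidth = 100L, glyphHeight = 40L,
    processSize = 24L,
    padding = 20L, margin = 40L, compartmentGap = 30L,
    compartmentOrder = c("nucleus", "er", "golgi", "cytoplasm",
                         "plasma_membrane", "extracellular_space")
  )
}

#' Read a layout configuration from YAML
#'
#' Values present in the file override [defaultLayoutConfig()].
#'
#' @param path YAML file.
#' @return A layout configuration list.
#' @export
readLayoutConfig <- function(path) {
  cfg <- defaultLayoutConfig()
  user <- yaml::read_yaml(path)
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  cfg
}

#' Assign deterministic grid-layout coordinates to a map
#'
#' Same input and configuration always produce identical integer
#' coordinates. Within each compartment, glyphs are sorted by
#' (class, label, id) and placed on a `columns`-wide grid; compartments
#' grow vertically to hold their glyphs (never overflow) and are stacked
#' bottom-to-top following `compartmentOrder`. Glyphs without a
#' compartment (Activity Flow maps) are gridded on the page directly.
#'
#' @param map An [SbgnMap].
#' @param config See [defaultLayoutConfig()].
#' @return The map with `x`/`y`/`w`/`h` filled in for all glyphs and
#'   compartments.
#' @export
layoutMap <- function(map, config = defaultLayoutConfig()) {
  stopifnot(is(map, "SbgnMap"))
  gl <- map@glyphs
  cp <- map@compartments
  cols <- as.integer(config$columns)
  if (cols < 1L) stop("layout config: columns must be >= 1", call. = FALSE)
  cw <- as.integer(config$cellWidth); ch <- as.integer(config$cellHeight)
  pad <- as.integer(config$padding); margin <- as.integer(config$margin)
  gap <- as.integer(config$compartmentGap)

  glyphDims <- function(cls) {
    if (cls == "process")
      c(as.integer(config$processSize), as.integer(config$processSize))
    else c(as.integer(config$glyphWidth), as.integer(config$glyphHeight))
  }

  ## deterministic compartment stacking: listed order is bottom-to-top,
  ## so we place the reversed order top-down
  inOrder <- intersect(config$compartmentOrder, cp$name)
  extra <- sort(setdiff(cp$name, inOrder))
  bottomUp <- c(inOrder, extra)
  topDown <- rev(bottomUp)

  compWidth <- cols * cw + 2L * pad
  placeGrid <- function(idx, originX, originY) {
    ## idx: glyph row indices already in final order
    for (k in seq_along(idx)) {
      i <- idx[k]
      row <- (k - 1L) %/% cols
      col <- (k - 1L) %% cols
      dims <- glyphDims(gl$class[i])
      gl$x[i] <<- originX + pad + col * cw + (cw - dims[1]) %/% 2L
      gl$y[i] <<- originY + pad + row * ch + (ch - dims[2]) %/% 2L
      gl$w[i] <<- dims[1]
      gl$h[i] <<- dims[2]
    }
  }

  yCursor <- margin
  for (nm in topDown) {
    j <- match(nm, cp$name)
    cid <- cp$id[j]
    idx <- which(!is.na(gl$compartment) & gl$compartment == cid)
    idx <- idx[order(gl$class[idx], gl$label[idx], gl$id[idx])]
    rows <- max(1L, ceiling(length(idx) / cols))
    height <- rows * ch + 2L * pad
    cp$x[j] <- margin; cp$y[j] <- yCursor
    cp$w[j] <- compWidth; cp$h[j] <- height
    placeGrid(idx, margin, yCursor)
    yCursor <- yCursor + height + gap
  }
  idx <- which(is.na(gl$compartment))
  if (length(idx) > 0L) {
    idx <- idx[order(gl$class[idx], gl$label[idx], gl$id[idx])]
    placeGrid(idx, margin, yCursor)
  }
  initialize(map, glyphs = gl, compartments = cp)
}
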
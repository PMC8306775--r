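## Literature-curation rules. An interactor enters the core layer only
## when identified in at least two small-scale experiments in human
## cells from independent references (distinct PMIDs), or acknowledged
## in at least two reviews from different research groups.
## High-throughput records never count towards core inclusion.

#' Apply the core-map inclusion rule to one interactor's evidence
#'
#' @param evidence data.frame of evidence records for one interactor
#'   (columns as in [readEvidenceTable()]).
#' @return One of `"two_small_scale"`, `"two_reviews"`, `"rejected"`.
#'   Small-scale support wins over review support when both hold.
#' @examples
#' ev <- data.frame(symbol = "SLC9A3R1", pmid = c(101L, 102L),
#'   evidence_class = "small_scale_experiment",
#'   method = "co-immunoprecipitation", cell_line = "HEK293",
#'   polarized_capable = FALSE, human_cells = TRUE,
#'   research_group = c("g1", "g2"))
#' passesInclusionRule(ev)   # "two_small_scale"
#' @export
passesInclusionRule <- function(evidence) {
  if (is.null(evidence) || nrow(evidence) == 0L) return("rejected")
  ss <- evidence$evidence_class == "small_scale_experiment" &
    evidence$human_cells
  if (length(unique(evidence$pmid[ss])) >= 2L) return("two_small_scale")
  rv <- evidence$evidence_class == "review"
  if (length(unique(evidence$research_group[rv])) >= 2L) return("two_reviews")
  "rejected"
}

#' Polarity provenance of one interactor's evidence
#'
#' `"polarized"` when any record comes from a cell line with the general
#' ability to polarize; `"non_polarized_only"` when cell-line-based
#' records exist but none is polarized; `"no_cell_evidence"` when the
#' evidence carries no cell line at all (e.g. reviews only).
#'
#' @inheritParams passesInclusionRule
#' @return One of `"polarized"`, `"non_polarized_only"`,
#'   `"no_cell_evidence"`.
#' @export
polarityStatus <- function(evidence) {
  if (is.null(evidence) || nrow(evidence) == 0L) return("no_cell_evidence")
  if (any(evidence$polarized_capable %in% TRUE)) return("polarized")
  cellBased <- !is.na(evidence$cell_line) & nzchar(evidence$cell_line)
  if (any(cellBased)) return("non_polarized_only")
  "no_cell_evidence"
}

#' Curate all interactors of a dataset
#'
#' Applies [passesInclusionRule()] and [polarityStatus()] to every
#' symbol with evidence records.
#'
#' @param dataset A [MapDataset], or an evidence data.frame.
#' @return data.frame with columns `symbol`, `accepted`, `basis`,
#'   `polarity_status` (one row per evidenced symbol, input order).
#' @export
curateInteractors <- function(dataset) {
  ev <- if (is(dataset, "MapDataset")) dataset@evidence else dataset
  syms <- unique(ev$symbol)
  basis <- character(length(syms))
  pol <- character(length(syms))
  for (i in seq_along(syms)) {
    sub <- ev[ev$symbol == syms[i], , drop = FALSE]
    basis[i] <- passesInclusionRule(sub)
    pol[i] <- polarityStatus(sub)
  }
  data.frame(symbol = syms, accepted = basis != "rejected", basis = basis,
             polarity_status = pol, stringsAsFactors = FALSE)
}

#' Per-submap entity counts and polarized-interactor percentages
#'
#' Summarizes each submap of the core layer: entity counts per species
#' kind, the number of interactors (evidenced entities), and the
#' percentage of interactors identified in at least one polarized cell
#' line. An entity assigned to k submaps contributes to all k.
#'
#' The percentage denominator is the set of interactors whose evidence
#' names a cell line at all (`polarized` + `non_polarized_only`);
#' entities known only from reviews or without cell provenance cannot be
#' classified either way and are excluded. Percentages are rounded
#' half-up to integers.
#'
#' @param dataset A [MapDataset].
#' @param layer Layer to summarize (default `"core"`).
#' @return data.frame with one row per submap: `submap`, one count
#'   column per species kind (`n_gene`, `n_rna`, ...), `n_entities`,
#'   `n_interactors`, `n_polarized`, `polarized_fraction` (0-100, `NA`
#'   when no interactor carries cell-line evidence).
#' @examples
#' fx <- packagedCftrFixture()
#' summarizeSubmaps(fx$dataset)[, c("submap", "polarized_fraction")]
#' @export
summarizeSubmaps <- function(dataset, layer = "core") {
  stopifnot(is(dataset, "MapDataset"))
  it <- dataset@interactors
  it <- it[it$layer == layer, , drop = FALSE]
  submaps <- unique(unlist(it$submaps))
  decisions <- curateInteractors(dataset)
  status <- setNames(decisions$polarity_status, decisions$symbol)
  evidenced <- decisions$symbol

  rows <- lapply(submaps, function(sm) {
    inSm <- vapply(it$submaps, function(s) sm %in% s, logical(1))
    sub <- it[inSm, , drop = FALSE]
    kinds <- table(factor(sub$species_kind, levels = speciesKinds()))
    ints <- intersect(sub$symbol, evidenced)
    st <- status[ints]
    nPol <- sum(st == "polarized")
    nNonPol <- sum(st == "non_polarized_only")
    frac <- if (nPol + nNonPol > 0L)
      .roundHalfUp(100 * nPol / (nPol + nNonPol)) else NA_real_
    cbind(data.frame(submap = sm, stringsAsFactors = FALSE),
          as.data.frame(t(setNames(as.integer(kinds),
                                   paste0("n_", names(kinds))))),
          data.frame(n_entities = nrow(sub), n_interactors = length(ints),
                     n_polarized = nPol, polarized_fraction = frac))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
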
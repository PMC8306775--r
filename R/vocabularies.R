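## Controlled vocabularies shared across the package. Unknown values in
## input tables are errors, never coerced.

#' Controlled vocabularies
#'
#' Registered values for the enumerated fields of a [MapDataset].
#' `mainCompartments()` returns the six principal cellular compartments;
#' the remaining compartments (vesicle, endosome, lysosome,
#' mitochondrion) are available but not flagged as main.
#'
#' @return Character vector of registered values.
#' @examples
#' speciesKinds()
#' mainCompartments()
#' @export
speciesKinds <- function() {
  c("gene", "rna", "protein", "truncated_protein", "receptor",
    "ion_channel", "complex", "simple_molecule", "ion", "degraded_pool")
}

#' @rdname speciesKinds
#' @export
compartmentNames <- function() {
  c("cytoplasm", "plasma_membrane", "extracellular_space", "nucleus",
    "er", "golgi", "vesicle", "endosome", "lysosome", "mitochondrion")
}

#' @rdname speciesKinds
#' @export
mainCompartments <- function() compartmentNames()[1:6]

#' @rdname speciesKinds
#' @export
evidenceClasses <- function() {
  c("small_scale_experiment", "review", "high_throughput")
}

#' @rdname speciesKinds
#' @export
reactionTypes <- function() {
  c("state_transition", "transcription", "translation", "transport",
    "complex_association", "complex_dissociation")
}

#' @rdname speciesKinds
#' @export
regulationTypes <- function() {
  c("catalysis", "inhibition", "physical_stimulation", "modulation")
}

#' @rdname speciesKinds
#' @export
identifierNamespaces <- function() {
  c("hgnc", "uniprot", "chebi", "pubchem_cid", "pmid")
}

## Per-namespace accession syntax (MIRIAM-style). Kept deliberately
## strict: curated annotation errors should fail loudly.
.idPatterns <- c(
  hgnc        = "^(HGNC:)?[0-9]+$",
  uniprot     = "^[A-Z0-9]{6,10}$",
  chebi       = "^(CHEBI:)?[0-9]+$",
  pubchem_cid = "^[0-9]+$",
  pmid        = "^[1-9][0-9]*$"
)

#' Check identifier accessions against their namespace syntax
#'
#' @param namespace One of [identifierNamespaces()].
#' @param accession Character vector of accessions.
#' @return Logical vector, `TRUE` where the accession is well-formed.
#' @examples
#' validIdentifier("uniprot", c("P13569", "???"))
#' @export
validIdentifier <- function(namespace, accession) {
  namespace <- match.arg(namespace, identifierNamespaces())
  grepl(.idPatterns[[namespace]], accession)
}

## half-up integer rounding (R's round() is half-even); used for the
## integer percentages of the submap summaries
.roundHalfUp <- function(x) floor(x + 0.5)

.assertEnum <- function(values, allowed, what) {
  bad <- setdiff(unique(values[!is.na(values) & nzchar(values)]), allowed)
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s value(s): %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

.splitField <- function(x, sep = ";") {
  lapply(x, function(v) {
    if (is.na(v) || !nzchar(v)) character(0)
    else unique(trimws(strsplit(v, sep, fixed = TRUE)[[1]]))
  })
}

.joinField <- function(x, sep = ";") {
  vapply(x, function(v) paste(v, collapse = sep), character(1))
}
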
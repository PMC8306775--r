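## Integration of the manually curated core layer with the
## high-throughput coarse layer: overlap computation, deduplication
## (shared symbols are kept in the core layer only) and cross-table
## consistency checks.

.canonSymbols <- function(symbols, aliases = NULL) {
  s <- toupper(trimws(symbols))
  s <- s[nzchar(s)]
  if (!is.null(aliases) && length(aliases) > 0L) {
    hit <- match(s, names(aliases))
    s[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
  }
  unique(s)
}

#' Overlap between the core and coarse interactor lists
#'
#' Symbols are uppercased, alias-resolved and deduplicated before the
#' set comparison, so the result is invariant to input order and
#' duplicates.
#'
#' @param core,coarse Character vectors of gene symbols.
#' @param aliases Optional named character vector (alias -> canonical).
#' @return A list of class `"layerOverlap"`: `core_only`, `shared`,
#'   `coarse_only` (pairwise disjoint symbol sets) and `counts`.
#' @examples
#' ov <- computeOverlap(c("CFTR", "VCP"), c("VCP", "HSPA8"))
#' ov$counts
#' @export
computeOverlap <- function(core, coarse, aliases = NULL) {
  core <- .canonSymbols(core, aliases)
  coarse <- .canonSymbols(coarse, aliases)
  shared <- intersect(core, coarse)
  out <- list(
    core_only = setdiff(core, coarse),
    shared = shared,
    coarse_only = setdiff(coarse, core)
  )
  out$counts <- c(core_only = length(out$core_only),
                  shared = length(out$shared),
                  coarse_only = length(out$coarse_only))
  structure(out, class = "layerOverlap")
}

#' @export
print.layerOverlap <- function(x, ...) {
  cat("Layer overlap: core-only", x$counts[["core_only"]],
      "| shared", x$counts[["shared"]],
      "| coarse-only", x$counts[["coarse_only"]], "\n")
  invisible(x)
}

#' Remove core-layer symbols from the coarse layer
#'
#' Shared interactors are kept in the manually curated core layer only;
#' this drops them from the coarse list. Idempotent.
#'
#' @param coarse Coarse-layer interactors: a character vector of
#'   symbols, or a data.frame with a `symbol` column.
#' @param core Character vector of core-layer symbols.
#' @param aliases Optional alias map (alias -> canonical).
#' @return The coarse input without symbols present in the core layer;
#'   the removed symbols are attached as attribute `"removed"`.
#' @export
dedupCoarse <- function(coarse, core, aliases = NULL) {
  core <- .canonSymbols(core, aliases)
  if (is.data.frame(coarse)) {
    syms <- toupper(trimws(coarse$symbol))
    if (!is.null(aliases) && length(aliases) > 0L) {
      hit <- match(syms, names(aliases))
      syms[!is.na(hit)] <- unname(aliases[hit[!is.na(hit)]])
    }
    keep <- !(syms %in% core)
    out <- coarse[keep, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "removed") <- unique(syms[!keep])
    return(out)
  }
  syms <- .canonSymbols(coarse, aliases)
  out <- setdiff(syms, core)
  attr(out, "removed") <- intersect(syms, core)
  out
}

#' Cross-table consistency checks
#'
#' Arithmetic checks across the dataset's tables: the per-submap
#' functional-category counts of the coarse layer must sum to the
#' deduplicated coarse size, the species-kind census must sum to the
#' entity total, and no category count may be negative. When `claimed`
#' counts are supplied (e.g. the category totals printed in a source
#' table), each is compared against the observed count.
#'
#' @param dataset A [MapDataset] holding the core layer.
#' @param coarse Coarse-layer interactor data.frame with columns
#'   `symbol`, `submap`, `functional_category` (pre-deduplication; core
#'   symbols are removed here).
#' @param claimed Optional named integer vector of claimed
#'   `submap/functional_category` counts (names like
#'   `"transcription/dna_replication"`).
#' @return data.frame with columns `check`, `expected`, `observed`,
#'   `pass`.
#' @examples
#' fx <- packagedCftrFixture()
#' rep <- consistencyReport(fx$dataset, fx$coarseTable,
#'                          claimed = fx$claimedCounts)
#' all(rep$pass)
#' @export
consistencyReport <- function(dataset, coarse = NULL, claimed = NULL) {
  stopifnot(is(dataset, "MapDataset"))
  checks <- list()
  addCheck <- function(name, expected, observed) {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, expected = expected, observed = observed,
      pass = isTRUE(expected == observed), stringsAsFactors = FALSE)
  }

  census <- entityCensus(dataset, layer = "core")
  addCheck("species_kind_counts_sum_to_entity_total",
           census$total, sum(census$counts))

  if (!is.null(coarse) && nrow(coarse) > 0L) {
    deduped <- dedupCoarse(coarse, dataset@interactors$symbol,
                           dataset@aliases)
    key <- paste(deduped$submap, deduped$functional_category, sep = "/")
    catCounts <- table(key)
    addCheck("coarse_category_counts_sum_to_deduped_size",
             nrow(deduped), sum(catCounts))
    addCheck("all_category_counts_nonnegative", 0L,
             sum(catCounts < 0L))
    if (!is.null(claimed)) {
      for (nm in names(claimed)) {
        obs <- if (nm %in% names(catCounts)) as.integer(catCounts[[nm]]) else 0L
        addCheck(paste0("claimed_count:", nm), as.integer(claimed[[nm]]), obs)
      }
      addCheck("claimed_counts_sum_to_deduped_size",
               as.integer(sum(claimed)), nrow(deduped))
    }
  }
  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  out
}
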
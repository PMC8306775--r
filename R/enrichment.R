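## Over-representation analysis of annotation terms in a gene list:
## hypergeometric upper-tail test per term, Benjamini-Hochberg
## correction across terms, deterministic ranking. This is a documented
## stand-in for proprietary semantic-network prioritization tools; the
## statistic is the classical ORA hypergeometric test.

#' Load a GMT gene-set file
#'
#' Standard GMT dialect: one term per line, tab-separated fields
#' `term id`, `description`, then member genes. Gene symbols are
#' uppercased and deduplicated within a term; genes outside the
#' supplied universe are dropped (with a message reporting the count),
#' and terms left empty after filtering are removed.
#'
#' @param path GMT file.
#' @param universe Optional background symbol set; defaults to the
#'   union of all genes in the file.
#' @return List of class `"annotationSet"`: `terms` (named list of
#'   gene-symbol vectors), `term_names` (named character), `universe`.
#' @export
loadGmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file does not exist: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L)
    stop("GMT parse error: line ", short[1], " has fewer than 3 fields",
         call. = FALSE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("GMT parse error: duplicate term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  descs <- vapply(fields, `[[`, character(1), 2L)
  genes <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  genes <- lapply(genes, function(g) g[nzchar(g)])
  if (!is.null(universe)) {
    universe <- unique(toupper(universe))
    dropped <- sum(vapply(genes, function(g) sum(!g %in% universe),
                          integer(1)))
    if (dropped > 0L)
      message("loadGmt: dropped ", dropped,
              " gene occurrence(s) outside the universe")
    genes <- lapply(genes, intersect, universe)
  } else {
    universe <- sort(unique(unlist(genes)))
  }
  keep <- lengths(genes) > 0L
  structure(list(
    terms = setNames(genes[keep], ids[keep]),
    term_names = setNames(descs[keep], ids[keep]),
    universe = universe
  ), class = "annotationSet")
}

#' Hypergeometric over-representation analysis
#'
#' For each term, tests whether the query gene list contains more term
#' members than expected under hypergeometric sampling from the
#' universe: `P(X >= overlap)` with population size `|universe|`,
#' `|term|` successes and `|query|` draws. P-values are adjusted across
#' all tested terms by Benjamini-Hochberg; ranks are strictly ordered
#' by (adjusted p, term id), so the output is deterministic.
#'
#' @param query Character vector of gene symbols; symbols outside the
#'   universe are dropped with a warning, and an empty query after
#'   filtering is an error.
#' @param annotation An `"annotationSet"` from [loadGmt()].
#' @return data.frame of class `"enrichmentResult"` with one row per
#'   term: `term`, `term_name`, `overlap`, `query_size`, `term_size`,
#'   `universe_size`, `p`, `p_adjust`, `percent_query`, `rank`;
#'   ordered by rank.
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines(c("T1\tfolding\tA\tB\tC", "T2\ttransport\tD\tE"), gmt)
#' annot <- loadGmt(gmt)
#' ora(c("A", "B"), annot)[1, c("term", "overlap", "p")]
#' @export
ora <- function(query, annotation) {
  stopifnot(inherits(annotation, "annotationSet"))
  query <- unique(toupper(query))
  outside <- setdiff(query, annotation$universe)
  if (length(outside) > 0L) {
    warning("ora: dropped ", length(outside),
            " query gene(s) outside the universe", call. = FALSE)
    query <- setdiff(query, outside)
  }
  if (length(query) == 0L)
    stop("ora: query is empty after universe filtering", call. = FALSE)
  N <- length(annotation$universe)
  n <- length(query)
  ids <- names(annotation$terms)
  K <- lengths(annotation$terms)
  k <- vapply(annotation$terms, function(g) length(intersect(g, query)),
              integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  padj <- p.adjust(p, method = "BH")
  out <- data.frame(
    term = ids,
    term_name = unname(annotation$term_names[ids]),
    overlap = as.integer(k), query_size = n, term_size = as.integer(K),
    universe_size = N, p = as.numeric(p), p_adjust = as.numeric(padj),
    percent_query = 100 * as.integer(k) / n,
    stringsAsFactors = FALSE)
  ord <- order(out$p_adjust, out$term)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("enrichmentResult", "data.frame")
  out
}

#' Compare the top-k terms of two enrichment results
#'
#' Set comparison of the top-`k` term ids of each ranked result.
#'
#' @param resultA,resultB `"enrichmentResult"` data.frames from [ora()],
#'   or any data.frames with `term` and `rank` columns.
#' @param k Number of top terms (`k` must not exceed either result).
#' @return List of class `"topTermComparison"`: `shared`, `only_a`,
#'   `only_b` (character vectors) and `counts`.
#' @export
compareTopTerms <- function(resultA, resultB, k) {
  topOf <- function(res) {
    if (!all(c("term", "rank") %in% names(res)))
      stop("enrichment result needs 'term' and 'rank' columns",
           call. = FALSE)
    if (k > nrow(res))
      stop("k exceeds the number of terms in a result", call. = FALSE)
    res$term[order(res$rank)][seq_len(k)]
  }
  a <- topOf(resultA); b <- topOf(resultB)
  out <- list(shared = intersect(a, b), only_a = setdiff(a, b),
              only_b = setdiff(b, a))
  out$counts <- c(shared = length(out$shared), only_a = length(out$only_a),
                  only_b = length(out$only_b))
  structure(out, class = "topTermComparison")
}

#' @export
print.topTermComparison <- function(x, ...) {
  cat("Top-term comparison: shared", x$counts[["shared"]],
      "| only A", x$counts[["only_a"]],
      "| only B", x$counts[["only_b"]], "\n")
  invisible(x)
}
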
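#' Gene-set over-representation analysis
#'
#' One-sided hypergeometric enrichment of a gene list against a
#' background universe for every set in a collection, with
#' Benjamini-Hochberg correction across the collection.  For a set with
#' `K` background members, a list of `n` genes and `k` list hits, the
#' p-value is the upper tail `P(X >= k)` of the hypergeometric
#' distribution with population `N = |background|`, and fold enrichment
#' is `(k/n) / (K/N)`.  The percent column is `100 * k / n` (the list is
#' the denominator).  This is a plain hypergeometric test; no EASE-style
#' deflation is applied.
#'
#' @param gene_list character vector of genes of interest (must be a
#'   subset of `background`).
#' @param background character vector: the analysis universe (e.g. the
#'   filtered probe/gene set). Sets are intersected with it.
#' @param collection named list of character vectors (gene sets), e.g.
#'   from [read_gmt()].
#' @return data.frame, one row per set, ordered by p-value: `set_name`,
#'   `count`, `percent`, `list_total`, `fold_enrichment`, `set_size`
#'   (in-background), `p`, `benjamini`.
#' @examples
#' bg <- paste0("g", 1:100)
#' sets <- list(A = paste0("g", 1:10), B = paste0("g", 11:40))
#' enrich(paste0("g", c(1:5, 50:54)), bg, sets)
#' @export
enrich <- function(gene_list, background, collection) {
  gene_list <- unique(gene_list)
  background <- unique(background)
  if (length(gene_list) == 0L || length(background) == 0L)
    stop("gene list and background must be non-empty")
  outside <- setdiff(gene_list, background)
  if (length(outside))
    stop("gene list contains genes outside the background: ",
         paste(utils::head(outside, 3), collapse = ", "))
  if (length(collection) == 0L || is.null(names(collection)) ||
      anyDuplicated(names(collection)))
    stop("collection must be a uniquely named list of gene sets")
  N <- length(background)
  n <- length(gene_list)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), background)
    K <- length(set)
    k <- length(intersect(gene_list, set))
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    fold <- if (K == 0L) NA_real_ else (k / n) / (K / N)
    data.frame(set_name = nm, count = k, percent = 100 * k / n,
               list_total = n, fold_enrichment = fold, set_size = K,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$benjamini <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
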
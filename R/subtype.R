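#' Match centroid genes to expression probes
#'
#' Restricts a centroid set and an expression matrix to the genes they
#' share, through an optional gene-to-probe map.  Genes mapping to
#' several probes are summarized by the mean (or median) of their probes;
#' unmapped genes are dropped and counted.
#'
#' @param centroids numeric genes x subtypes matrix with gene rownames.
#' @param matrix numeric probes x samples expression matrix.
#' @param id_map data.frame with columns `gene_id`, `probe_id`
#'   (one-to-many allowed); `NULL` (default) means probe ids are already
#'   gene ids.
#' @param aggregate `"mean"` (default) or `"median"` across a gene's
#'   probes.
#' @return A list: `centroids` and `matrix` restricted to matched genes
#'   (same row order), `report` with `n_matched` and `n_dropped` and the
#'   dropped gene ids.
#' @export
match_genes <- function(centroids, matrix, id_map = NULL,
                        aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  genes <- rownames(centroids)
  if (is.null(genes)) stop("centroids must have gene rownames")
  if (is.null(id_map))
    id_map <- data.frame(gene_id = rownames(matrix),
                         probe_id = rownames(matrix),
                         stringsAsFactors = FALSE)
  id_map <- id_map[id_map$gene_id %in% genes &
                     id_map$probe_id %in% rownames(matrix), , drop = FALSE]
  matched <- intersect(genes, unique(id_map$gene_id))
  if (length(matched) < 2L)
    stop("fewer than two centroid genes matched the expression matrix")
  agg_fun <- if (aggregate == "mean") colMeans else
    function(m) apply(m, 2L, stats::median)
  expr <- t(vapply(matched, function(g) {
    probes <- id_map$probe_id[id_map$gene_id == g]
    agg_fun(matrix[probes, , drop = FALSE])
  }, numeric(ncol(matrix))))
  colnames(expr) <- colnames(matrix)
  dropped <- setdiff(genes, matched)
  list(centroids = centroids[matched, , drop = FALSE], matrix = expr,
       report = list(n_matched = length(matched),
                     n_dropped = length(dropped), dropped = dropped))
}

#' Nearest-centroid molecular subtype classification
#'
#' Assigns a sample to the subtype whose centroid it correlates with best
#' by Spearman rank correlation (average ranks for ties); a sample whose
#' maximum correlation falls below `min_corr` is Unclassified.  Because
#' Spearman works on ranks across genes, classification is invariant to
#' any strictly increasing transform of the sample vector.  Ties between
#' subtypes go to the lexicographically smallest label and are recorded.
#'
#' @param sample_values numeric vector over the matched genes (same order
#'   as `centroids` rows).
#' @param centroids numeric genes x subtypes matrix.
#' @param min_corr unclassified threshold on the maximum correlation.
#'   Default 0.2.
#' @param sample_id optional identifier.
#' @return A list of class `subtype_call`: `sample_id`, `label`
#'   (`"Unclassified"` when below threshold or undefined),
#'   `correlations` (named, per subtype; `NA` when undefined),
#'   `max_correlation`, `tied` (labels tied at the maximum, if any).
#' @export
classify <- function(sample_values, centroids, min_corr = 0.2,
                     sample_id = NA_character_) {
  if (length(sample_values) != nrow(centroids))
    stop("sample vector and centroids must cover the same genes")
  if (ncol(centroids) < 2L) stop("need at least two subtype centroids")
  labels <- colnames(centroids)
  if (stats::sd(sample_values) == 0) {
    cors <- stats::setNames(rep(NA_real_, length(labels)), labels)
    return(structure(list(sample_id = sample_id, label = "Unclassified",
                          correlations = cors,
                          max_correlation = NA_real_,
                          tied = character(0)),
                     class = "subtype_call"))
  }
  cors <- vapply(labels, function(lab)
    stats::cor(sample_values, centroids[, lab], method = "spearman"),
    numeric(1))
  mx <- max(cors)
  tied <- sort(labels[cors == mx])
  label <- if (mx < min_corr) "Unclassified" else tied[1]
  structure(list(sample_id = sample_id, label = label,
                 correlations = cors, max_correlation = mx,
                 tied = if (length(tied) > 1L) tied else character(0)),
            class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  cat("subtype call", if (!is.na(x$sample_id)) paste0(" [", x$sample_id, "]"),
      ": ", x$label,
      if (!is.na(x$max_correlation))
        paste0(" (max rho = ", format(x$max_correlation, digits = 3), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Classify every column of an expression matrix
#'
#' @param matrix numeric genes x samples matrix over the matched genes.
#' @inheritParams classify
#' @return data.frame: `sample_id`, `label`, `max_correlation`, plus one
#'   correlation column per subtype.
#' @export
classify_samples <- function(matrix, centroids, min_corr = 0.2) {
  calls <- lapply(seq_len(ncol(matrix)), function(j)
    classify(matrix[, j], centroids, min_corr = min_corr,
             sample_id = colnames(matrix)[j] %||% paste0("S", j)))
  out <- data.frame(
    sample_id = vapply(calls, `[[`, character(1), "sample_id"),
    label = vapply(calls, `[[`, character(1), "label"),
    max_correlation = vapply(calls, `[[`, numeric(1), "max_correlation"),
    stringsAsFactors = FALSE)
  cormat <- t(vapply(calls, `[[`, numeric(ncol(centroids)), "correlations"))
  colnames(cormat) <- paste0("rho_", colnames(centroids))
  cbind(out, as.data.frame(cormat, row.names = seq_len(nrow(out))))
}

#' Per-patient subtype concordance
#'
#' Groups subtype calls by patient and flags each patient concordant when
#' all classified members (tumor and xenograft passages) share one label.
#' Unclassified calls are excluded from the vote but listed; a patient
#' with fewer than two classified calls gets `NA` (vote undefined).
#'
#' @param calls data.frame with columns `sample_id`, `label` (from
#'   [classify_samples()]) plus `patient` and optionally `role`.
#' @return data.frame: `patient`, `n_calls`, `n_classified`, `labels`
#'   (comma-joined, in input order), `concordant`.
#' @export
concordance_report <- function(calls) {
  if (!all(c("patient", "label") %in% names(calls)))
    stop("calls must have patient and label columns")
  patients <- unique(calls$patient)
  rows <- lapply(patients, function(p) {
    lab <- calls$label[calls$patient == p]
    cls <- lab[lab != "Unclassified"]
    data.frame(patient = p, n_calls = length(lab),
               n_classified = length(cls),
               labels = paste(lab, collapse = ","),
               concordant = if (length(cls) >= 2L)
                 length(unique(cls)) == 1L else NA,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
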
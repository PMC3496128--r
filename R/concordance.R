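#' Pairwise GNL correlation on altered clones
#'
#' Pearson correlation between the 3-level (gain/normal/loss) status
#' vectors of a tumor and its xenograft, restricted to clones that are
#' non-missing in both profiles and altered (non-normal) in at least one
#' of the two (`altered_in = "either"`, the default) or in both
#' (`altered_in = "both"`).  Amplification is collapsed to gain first
#' unless `collapse = FALSE` is given, in which case the 4-level codes are
#' correlated as-is.
#'
#' The correlation is undefined (returned as `NA` with `defined = FALSE`)
#' when fewer than two eligible clones remain or either restricted vector
#' has zero variance; it is never reported as 0 in those cases.
#'
#' @param a,b integer status vectors over a common clone map.
#' @param altered_in `"either"` or `"both"`: which profiles must be
#'   altered for a clone to enter the correlation.
#' @param collapse collapse amplification to gain first? Default `TRUE`.
#' @param pair_id optional identifier carried into the result.
#' @return A list of class `concordance_result`: `pair_id`, `R`,
#'   `n_altered_clones`, `defined`.
#' @examples
#' gnl_correlation(c(1L, 1L, 0L, -1L), c(1L, 1L, 0L, -1L))$R  # 1
#' @export
gnl_correlation <- function(a, b, altered_in = c("either", "both"),
                            collapse = TRUE, pair_id = NA_character_) {
  altered_in <- match.arg(altered_in)
  if (length(a) != length(b))
    stop("profiles must share a clone map (equal length)")
  check_status_codes(a); check_status_codes(b)
  if (collapse) {
    a <- collapse_amplification(a)
    b <- collapse_amplification(b)
  }
  ok <- !is.na(a) & !is.na(b)
  alt <- if (altered_in == "either") (a != 0L | b != 0L) else
    (a != 0L & b != 0L)
  sel <- which(ok & alt)
  res <- list(pair_id = pair_id, R = NA_real_,
              n_altered_clones = length(sel), defined = FALSE)
  if (length(sel) >= 2L &&
      stats::sd(a[sel]) > 0 && stats::sd(b[sel]) > 0) {
    res$R <- stats::cor(a[sel], b[sel])
    res$defined <- TRUE
  }
  class(res) <- "concordance_result"
  res
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("GNL concordance", if (!is.na(x$pair_id)) paste0(" [", x$pair_id, "]"),
      ": R = ", if (x$defined) format(x$R, digits = 3) else "undefined",
      " over ", x$n_altered_clones, " altered clones\n", sep = "")
  invisible(x)
}

#' Cohort concordance table
#'
#' Applies [gnl_correlation()] to every tumor/xenograft pair of a cohort.
#'
#' @param tumor,xenograft status matrices (clones x pairs, same clone
#'   order); columns are matched through `pairs`.
#' @param pairs data.frame with columns `pair_id`, `tumor`, `xenograft`
#'   naming columns of the two matrices.
#' @param ... passed to [gnl_correlation()].
#' @return data.frame with `pair_id`, `R`, `n_altered_clones`, `defined`.
#' @export
concordance_table <- function(tumor, xenograft, pairs, ...) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- gnl_correlation(tumor[, pairs$tumor[i]],
                         xenograft[, pairs$xenograft[i]],
                         pair_id = pairs$pair_id[i], ...)
    data.frame(pair_id = r$pair_id, R = r$R,
               n_altered_clones = r$n_altered_clones,
               defined = r$defined, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation distance matrix over status profiles
#'
#' Distance `d(i, j) = 1 - Pearson(status_i, status_j)` computed over all
#' clones non-missing in both profiles (no altered-clone restriction:
#' cohort clustering uses the full grid).  An undefined correlation (fewer
#' than two shared clones, or zero variance) is an error naming the
#' offending pair.
#'
#' @param profiles integer status matrix, clones x samples (>= 2 samples).
#' @param collapse collapse amplification to gain first? Default `TRUE`.
#' @return Symmetric numeric matrix with zero diagonal and sample
#'   dimnames.
#' @export
correlation_distance_matrix <- function(profiles, collapse = TRUE) {
  if (is.null(dim(profiles)) || ncol(profiles) < 2L)
    stop("need a status matrix with at least two samples")
  check_status_codes(profiles)
  if (collapse) profiles <- collapse_amplification(profiles)
  ids <- colnames(profiles) %||% paste0("S", seq_len(ncol(profiles)))
  n <- ncol(profiles)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(profiles[, i]) & !is.na(profiles[, j])
    x <- profiles[ok, i]; y <- profiles[ok, j]
    if (sum(ok) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("correlation undefined for pair (", ids[i], ", ", ids[j], ")")
    d[i, j] <- d[j, i] <- 1 - stats::cor(x, y)
  }
  d
}

#' Group-average (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering with group-average linkage on a precomputed
#' distance matrix, as used for cohort copy-number dendrograms.  Merge
#' ties are broken deterministically: among equally close cluster pairs,
#' the pair whose (lexicographically smallest member label of each
#' cluster) sorts first is merged.  The result is a standard `hclust`
#' object whose heights are the group-average distances at each merge.
#'
#' @param d symmetric distance matrix with sample dimnames (a `dist`
#'   object is also accepted).
#' @return An object of class `hclust` (single-sample input yields a
#'   zero-merge degenerate tree).
#' @seealso [write_dendrogram()] for Newick export,
#'   [count_cosegregating_pairs()].
#' @export
cluster_profiles <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("d must be a square distance matrix")
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
    stop("d must be symmetric with zero diagonal")
  labels <- rownames(d) %||% paste0("S", seq_len(nrow(d)))
  n <- nrow(d)
  out <- list(merge = matrix(integer(0), 0L, 2L), height = numeric(0),
              order = seq_len(n), labels = labels, method = "average",
              call = match.call(), dist.method = "pearson")
  class(out) <- "hclust"
  if (n == 1L) return(out)

  # active clusters: id (negative leaf index or positive merge row),
  # size, representative label (lexicographically smallest member)
  act_id <- -seq_len(n)
  act_size <- rep(1L, n)
  act_lab <- labels
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(act_id)
    best <- NULL
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      li <- sort(c(act_lab[i], act_lab[j]))
      cand <- list(i = i, j = j, d = D[i, j], lab = li)
      if (is.null(best) || cand$d < best$d - 1e-15 ||
          (abs(cand$d - best$d) <= 1e-15 &&
           (cand$lab[1] < best$lab[1] ||
            (cand$lab[1] == best$lab[1] && cand$lab[2] < best$lab[2]))))
        best <- cand
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(act_id[i], act_id[j]))
    height[step] <- best$d
    # group-average update against every other cluster
    ni <- act_size[i]; nj <- act_size[j]
    newrow <- (ni * D[i, ] + nj * D[j, ]) / (ni + nj)
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newrow[keep]),
               c(newrow[keep], 0))
    act_id <- c(act_id[keep], step)
    act_size <- c(act_size[keep], ni + nj)
    act_lab <- c(act_lab[keep], min(best$lab))
  }
  out$merge <- merge
  out$height <- height
  out$order <- hclust_order(merge, n)
  out
}

# leaf ordering by left-to-right traversal of the merge tree
hclust_order <- function(merge, n) {
  leaves <- function(node) {
    if (node < 0L) return(-node)
    c(leaves(merge[node, 1L]), leaves(merge[node, 2L]))
  }
  leaves(nrow(merge))
}

# leaf labels below each internal node
node_leaves <- function(hc) {
  n1 <- nrow(hc$merge)
  res <- vector("list", n1)
  for (k in seq_len(n1)) {
    kids <- hc$merge[k, ]
    res[[k]] <- c(
      if (kids[1] < 0) hc$labels[-kids[1]] else res[[kids[1]]],
      if (kids[2] < 0) hc$labels[-kids[2]] else res[[kids[2]]])
  }
  res
}

#' Count tumor/xenograft pairs that co-segregate in a dendrogram
#'
#' A pair co-segregates when its two samples are sister leaves: their
#' lowest common ancestor in the merge tree has exactly those two leaves
#' below it.  This is the strict reading of a tumor and its xenograft
#' "clustering together".
#'
#' @param hc an `hclust` tree containing all pair members as leaves.
#' @param pairs data.frame with columns `pair_id`, `tumor`, `xenograft`
#'   (leaf labels).
#' @return Integer count, with attribute `"cosegregating"` listing the
#'   pair_ids that co-segregate.
#' @export
count_cosegregating_pairs <- function(hc, pairs) {
  if (!inherits(hc, "hclust")) stop("hc must be an hclust tree")
  missing <- setdiff(c(pairs$tumor, pairs$xenograft), hc$labels)
  if (length(missing))
    stop("sample(s) not in dendrogram: ", paste(missing, collapse = ", "))
  sisters <- list()
  if (nrow(hc$merge) > 0) {
    both_leaf <- hc$merge[, 1] < 0 & hc$merge[, 2] < 0
    sisters <- lapply(which(both_leaf), function(k)
      sort(hc$labels[-hc$merge[k, ]]))
  }
  hit <- vapply(seq_len(nrow(pairs)), function(i) {
    key <- sort(c(pairs$tumor[i], pairs$xenograft[i]))
    any(vapply(sisters, identical, logical(1), y = key))
  }, logical(1))
  structure(sum(hit), cosegregating = pairs$pair_id[hit])
}
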
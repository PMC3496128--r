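#' Filter low-signal probe sets
#'
#' Removes probe sets whose log2 signal cannot be distinguished from
#' noise: a probe is kept iff the fraction of samples in which its value
#' lies below `floor` is at most `max_below_fraction`.  With the defaults
#' (floor 3.5, fraction 0.85) a probe below 3.5 in no more than 85% of
#' samples is retained; the boundary is inclusive (exactly 85% below
#' keeps the probe).
#'
#' @param matrix numeric probes x samples matrix, log2 scale.
#' @param floor log2 detection threshold. Default 3.5.
#' @param max_below_fraction maximum tolerated below-floor fraction.
#'   Default 0.85.
#' @return A list: `matrix` (kept rows), `kept` and `removed` (probe id
#'   vectors), `n_kept`, `n_removed`.
#' @export
filter_probesets <- function(matrix, floor = 3.5,
                             max_below_fraction = 0.85) {
  if (is.null(dim(matrix)) || nrow(matrix) == 0L || ncol(matrix) == 0L)
    stop("expression matrix is empty")
  if (!(max_below_fraction > 0 && max_below_fraction <= 1))
    stop("max_below_fraction must lie in (0, 1]")
  frac_below <- rowMeans(matrix < floor)
  keep <- frac_below <= max_below_fraction
  ids <- rownames(matrix) %||% as.character(seq_len(nrow(matrix)))
  list(matrix = matrix[keep, , drop = FALSE],
       kept = ids[keep], removed = ids[!keep],
       n_kept = sum(keep), n_removed = sum(!keep))
}

#' Paired differential expression by regression residual percentiles
#'
#' Fits an ordinary least-squares regression of the xenograft profile on
#' the tumor profile (slope and intercept) under the null hypothesis that
#' the pair's expression profiles are similar, and flags probes whose
#' residual falls outside the empirical `lo_pct`/`hi_pct` percentiles of
#' the residual distribution.  Residuals are oriented so a positive value
#' means higher expression in the xenograft; probes strictly above the
#' upper threshold are "over" (xenograft-overexpressed), strictly below
#' the lower threshold "under".  With distinct residuals and the default
#' 5th/95th percentiles this flags exactly 10% of probes.  A degenerate
#' all-equal residual distribution flags nothing.
#'
#' @param tumor_values,xeno_values equal-length numeric vectors over the
#'   filtered probe universe (>= 20 probes), log2 scale.
#' @param lo_pct,hi_pct percentile bounds (defaults 5 and 95). Empirical
#'   percentiles use the linearly interpolated order statistic
#'   (`stats::quantile` type 7).
#' @param pair_id optional identifier carried into the result.
#' @return A list of class `pair_de_result`: `pair_id`, `over_probes`,
#'   `under_probes`, `residuals` (named), `thresholds` (lo, hi),
#'   `coefficients` (intercept, slope).
#' @export
paired_outliers <- function(tumor_values, xeno_values, lo_pct = 5,
                            hi_pct = 95, pair_id = NA_character_) {
  n <- length(tumor_values)
  if (length(xeno_values) != n)
    stop("tumor and xenograft vectors must have equal length")
  if (n < 20L) stop("need at least 20 probes for residual percentiles")
  if (anyNA(tumor_values) || anyNA(xeno_values))
    stop("missing values not supported; filter first")
  if (!(lo_pct > 0 && hi_pct < 100 && lo_pct < hi_pct))
    stop("require 0 < lo_pct < hi_pct < 100")
  if (stats::sd(tumor_values) == 0)
    stop("zero variance in tumor values; regression undefined")
  ids <- names(tumor_values) %||% as.character(seq_len(n))
  slope <- stats::cov(tumor_values, xeno_values) /
    stats::var(tumor_values)
  intercept <- mean(xeno_values) - slope * mean(tumor_values)
  res <- xeno_values - (intercept + slope * tumor_values)
  names(res) <- ids
  thr <- stats::quantile(res, c(lo_pct, hi_pct) / 100, names = FALSE)
  degenerate <- diff(range(res)) < .Machine$double.eps^0.5
  over <- if (degenerate) character(0) else ids[res > thr[2]]
  under <- if (degenerate) character(0) else ids[res < thr[1]]
  structure(list(pair_id = pair_id, over_probes = over,
                 under_probes = under, residuals = res,
                 thresholds = c(lo = thr[1], hi = thr[2]),
                 coefficients = c(intercept = intercept, slope = slope)),
            class = "pair_de_result")
}

#' Assemble a pair DE result from precomputed outlier sets
#'
#' Constructor for `pair_de_result` objects when the over/under probe
#' sets come from an external analysis (e.g. a published per-pair outlier
#' list) rather than from [paired_outliers()], so they can enter
#' [recurrence_table()] and downstream summaries.
#'
#' @param pair_id identifier of the comparison.
#' @param over_probes,under_probes disjoint character vectors of probe
#'   ids, both subsets of `universe`.
#' @param universe character vector of all probes in the analysis.
#' @return A `pair_de_result` (with zero placeholder residuals).
#' @export
pair_de_result <- function(pair_id, over_probes, under_probes, universe) {
  if (length(intersect(over_probes, under_probes)))
    stop("over and under sets must be disjoint")
  if (!all(c(over_probes, under_probes) %in% universe))
    stop("outlier probes must belong to the universe")
  res <- structure(numeric(length(universe)), names = universe)
  structure(list(pair_id = pair_id, over_probes = over_probes,
                 under_probes = under_probes, residuals = res,
                 thresholds = c(lo = NA_real_, hi = NA_real_),
                 coefficients = c(intercept = NA_real_, slope = NA_real_)),
            class = "pair_de_result")
}

#' @export
print.pair_de_result <- function(x, ...) {
  cat("paired DE", if (!is.na(x$pair_id)) paste0(" [", x$pair_id, "]"),
      ": ", length(x$over_probes), " over / ", length(x$under_probes),
      " under of ", length(x$residuals), " probes\n", sep = "")
  invisible(x)
}

#' Expression stability between xenograft passages
#'
#' Identical contract to [paired_outliers()], with two passages of the
#' same xenograft as the pair: residual outliers are probes whose
#' expression drifted between passages.
#'
#' @inheritParams paired_outliers
#' @param xeno_early,xeno_late expression vectors of the earlier and
#'   later passage.
#' @return A `pair_de_result`; positive residuals mean higher in the
#'   later passage.
#' @export
passage_stability <- function(xeno_early, xeno_late, lo_pct = 5,
                              hi_pct = 95, pair_id = NA_character_) {
  paired_outliers(xeno_early, xeno_late, lo_pct = lo_pct, hi_pct = hi_pct,
                  pair_id = pair_id)
}

#' Cross-pair recurrence of differentially expressed probes
#'
#' For every probe flagged in at least one pair, counts the number of
#' pairs `k` in which it is an outlier (either direction) and classifies
#' its direction at that level by majority sign among the flagging pairs;
#' ties count as under-expressed (`tie` controls this).  Returns exact-k
#' counts with the direction split and percentages of the probe universe.
#'
#' @param results list of `pair_de_result` objects over a common filtered
#'   probe universe.
#' @param universe character vector of all probes in the analysis (the
#'   filtered universe); defaults to the union of residual names across
#'   results, but should be supplied explicitly so percentages use the
#'   full analysis universe.
#' @param tie direction assigned when a probe is flagged over and under
#'   equally often: `"under"` (default) or `"over"`.
#' @return A list of class `recurrence_table`: `table` (data.frame `k`,
#'   `n_probes`, `n_over`, `n_under`, `pct_universe`), `per_probe`
#'   (data.frame `probe`, `k`, `n_over`, `n_under`, `direction`),
#'   `universe_size`, `n_pairs`.
#' @export
recurrence_table <- function(results, universe = NULL, tie = c("under", "over")) {
  tie <- match.arg(tie)
  if (length(results) < 1L) stop("need at least one pair result")
  if (!all(vapply(results, inherits, logical(1), "pair_de_result")))
    stop("results must be pair_de_result objects")
  universes <- lapply(results, function(r) sort(names(r$residuals)))
  if (length(unique(universes)) != 1L)
    stop("pair results use inconsistent probe universes")
  if (is.null(universe)) universe <- universes[[1]]
  bad <- setdiff(universes[[1]], universe)
  if (length(bad))
    stop("probes outside the declared universe: ", bad[1], " ...")
  n_pairs <- length(results)
  over_tab <- table(unlist(lapply(results, `[[`, "over_probes")))
  under_tab <- table(unlist(lapply(results, `[[`, "under_probes")))
  probes <- union(names(over_tab), names(under_tab))
  n_over <- as.integer(over_tab[probes]); n_over[is.na(n_over)] <- 0L
  n_under <- as.integer(under_tab[probes]); n_under[is.na(n_under)] <- 0L
  k <- n_over + n_under
  direction <- ifelse(n_over > n_under, "over",
               ifelse(n_under > n_over, "under", tie))
  per_probe <- data.frame(probe = probes, k = k, n_over = n_over,
                          n_under = n_under, direction = direction,
                          stringsAsFactors = FALSE)
  tab <- data.frame(k = seq_len(n_pairs))
  tab$n_probes <- vapply(tab$k, function(kk) sum(k == kk), integer(1))
  tab$n_over <- vapply(tab$k, function(kk)
    sum(k == kk & direction == "over"), integer(1))
  tab$n_under <- vapply(tab$k, function(kk)
    sum(k == kk & direction == "under"), integer(1))
  tab$pct_universe <- 100 * tab$n_probes / length(universe)
  structure(list(table = tab, per_probe = per_probe,
                 universe_size = length(universe), n_pairs = n_pairs),
            class = "recurrence_table")
}

#' @export
print.recurrence_table <- function(x, ...) {
  cat("recurrence over ", x$n_pairs, " pairs, universe ",
      x$universe_size, " probes; ", sum(x$table$n_probes),
      " probes flagged in >= 1 pair\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Chi-square trend in outlier direction across recurrence classes
#'
#' Tests whether the proportion of over- versus under-expressed probes
#' differs between two recurrence classes (e.g. probes exclusive to one
#' pair versus probes common to many pairs) with a Pearson chi-square on
#' the 2x2 table of direction counts, without continuity correction.
#'
#' @param table a `recurrence_table`.
#' @param class_a,class_b integer vectors of recurrence levels `k`
#'   defining the two classes (e.g. `1` and `10:13`).
#' @return A list: `statistic`, `p_value`, `df`, `counts` (the 2x2
#'   table, rows = classes, columns = over/under).
#' @export
direction_trend_chisq <- function(table, class_a, class_b) {
  if (!inherits(table, "recurrence_table"))
    stop("table must be a recurrence_table")
  tab <- table$table
  counts <- rbind(
    a = c(over = sum(tab$n_over[tab$k %in% class_a]),
          under = sum(tab$n_under[tab$k %in% class_a])),
    b = c(over = sum(tab$n_over[tab$k %in% class_b]),
          under = sum(tab$n_under[tab$k %in% class_b])))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chi-square undefined: a margin of the 2x2 table is zero")
  # the asymptotic statistic is wanted even for small tables; the
  # small-expected-count warning is not informative here
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter), counts = counts)
}
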
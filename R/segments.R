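#' Define constant-status chromosomal segments across a cohort
#'
#' Partitions the clone grid into maximal genomic segments over which
#' every sample in the cohort has constant copy-number status: a
#' breakpoint is placed between two consecutive clones of a chromosome
#' whenever any sample's status changes between them, and chromosome
#' boundaries always break.  Missing calls never induce breakpoints: for
#' each sample a change is declared only between its two nearest
#' non-missing values, and the break is placed immediately before the
#' later one.
#'
#' By default statuses are collapsed to the 3-level gain/normal/loss
#' encoding before segmentation (`collapse = TRUE`); pass `FALSE` to
#' segment on the 4-level codes so amplification boundaries also break.
#'
#' @param profiles integer status matrix, clones x samples (>= 1 sample).
#' @param clone_map a [clone_map()] matching the rows of `profiles`.
#' @param collapse collapse amplification to gain first? Default `TRUE`.
#' @return data.frame of class `segment_table`: `segment_id`, `chrom`,
#'   `start`, `end` (base pairs: first clone's start to last clone's
#'   end), `first_clone`, `last_clone` (row indices into `clone_map`),
#'   `n_clones`.
#' @export
define_segments <- function(profiles, clone_map, collapse = TRUE) {
  if (is.null(dim(profiles)) || ncol(profiles) < 1L)
    stop("need a status matrix with at least one sample")
  profiles <- check_profiles(profiles, clone_map)
  check_status_codes(profiles)
  if (collapse) profiles <- collapse_amplification(profiles)
  n <- nrow(clone_map)
  # breakpoint[i] == TRUE: break between clone i and clone i+1
  brk <- logical(max(n - 1L, 0L))
  if (n > 1L) {
    same_chr <- clone_map$chrom[-n] == clone_map$chrom[-1L]
    brk[!same_chr] <- TRUE
    for (s in seq_len(ncol(profiles))) {
      v <- profiles[, s]
      obs <- which(!is.na(v))
      if (length(obs) < 2L) next
      # consecutive non-missing observations on the same chromosome
      a <- obs[-length(obs)]; b <- obs[-1L]
      chg <- clone_map$chrom[a] == clone_map$chrom[b] & v[a] != v[b]
      brk[b[chg] - 1L] <- TRUE
    }
  }
  seg_start <- c(1L, which(brk) + 1L)
  seg_end <- c(which(brk), n)
  out <- data.frame(
    segment_id = sprintf("seg%04d", seq_along(seg_start)),
    chrom = clone_map$chrom[seg_start],
    start = clone_map$start[seg_start],
    end = clone_map$end[seg_end],
    first_clone = seg_start, last_clone = seg_end,
    n_clones = seg_end - seg_start + 1L,
    stringsAsFactors = FALSE)
  class(out) <- c("segment_table", "data.frame")
  out
}

#' Status of a profile over one segment
#'
#' Lifts clone-level status to a segment from [define_segments()]: the
#' constant non-missing status of the member clones, or missing when all
#' member clones are missing.  Disagreement among non-missing member
#' clones means the profile was not part of the cohort that defined the
#' segment and is an error.
#'
#' @param profile integer status vector over the segment's clone map.
#' @param segment one row of a `segment_table`.
#' @return A single status code (or `NA`).
#' @export
segment_status <- function(profile, segment) {
  vals <- profile[segment$first_clone:segment$last_clone]
  vals <- unique(vals[!is.na(vals)])
  if (length(vals) == 0L) return(NA_integer_)
  if (length(vals) > 1L)
    stop("member clones disagree in segment ", segment$segment_id,
         "; profile is not from the defining cohort")
  vals
}

#' Per-segment GNL difference between xenograft and tumor
#'
#' The signed change in status over a segment:
#' `sign(status_xenograft - status_tumor)` on collapsed 3-level codes, so
#' +1 means increased copy number in the xenograft, -1 decreased, 0 no
#' change, `NA` when either side is missing over the segment.
#'
#' @param tumor,xenograft status vectors (3-level; apply
#'   [collapse_amplification()] first if needed).
#' @param segment one row of a `segment_table`.
#' @return -1, 0, +1 or `NA`.
#' @export
gnl_difference <- function(tumor, xenograft, segment) {
  st <- segment_status(tumor, segment)
  sx <- segment_status(xenograft, segment)
  if (is.na(st) || is.na(sx)) return(NA_integer_)
  as.integer(sign(sx - st))
}

#' Recurrence thresholds for GNL-difference calling
#'
#' @param min_pair_fraction minimum fraction of present (non-missing)
#'   comparisons that must show a difference of a given sign for a
#'   segment to be called recurrently gained or lost. Default 0.30.
#' @param min_comparisons minimum number of present comparisons for a
#'   segment to be eligible at all. Default 10.
#' @return A list of class `recurrence_config`.
#' @export
recurrence_config <- function(min_pair_fraction = 0.30,
                              min_comparisons = 10L) {
  if (!(min_pair_fraction > 0 && min_pair_fraction <= 1))
    stop("min_pair_fraction must lie in (0, 1]")
  if (min_comparisons < 1L) stop("min_comparisons must be >= 1")
  structure(list(min_pair_fraction = min_pair_fraction,
                 min_comparisons = as.integer(min_comparisons)),
            class = "recurrence_config")
}

#' GNL-difference matrix over all segments and pairs
#'
#' @param tumor,xenograft status matrices (clones x pairs); amplification
#'   is collapsed internally.
#' @param pairs data.frame `pair_id`, `tumor`, `xenograft` naming columns.
#' @param segments a `segment_table` from [define_segments()].
#' @return Integer matrix segments x pairs of GNL differences.
#' @export
gnl_difference_matrix <- function(tumor, xenograft, pairs, segments) {
  tumor <- collapse_amplification(tumor)
  xenograft <- collapse_amplification(xenograft)
  diffs <- matrix(NA_integer_, nrow(segments), nrow(pairs),
                  dimnames = list(segments$segment_id, pairs$pair_id))
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    for (j in seq_len(nrow(pairs)))
      diffs[i, j] <- gnl_difference(tumor[, pairs$tumor[j]],
                                    xenograft[, pairs$xenograft[j]], seg)
  }
  diffs
}

#' Recurrent xenograft-specific copy-number differences
#'
#' Calls segments whose GNL difference recurs across pairs.  A segment is
#' "present" in a comparison when its difference is non-missing for that
#' pair; it is eligible when present in at least `min_comparisons`
#' comparisons; an eligible segment is called gained (lost) when positive
#' (negative) differences occur in at least `min_pair_fraction` of its
#' present comparisons.  A segment can be called in both directions.
#'
#' @param tumor,xenograft status matrices (clones x pairs).
#' @param pairs data.frame `pair_id`, `tumor`, `xenograft`.
#' @param segments a `segment_table`; computed from the cohort via
#'   [define_segments()] if omitted.
#' @param config a [recurrence_config()].
#' @param clone_map required when `segments` is omitted.
#' @return A list of class `recurrent_region_report`: `report` (per
#'   segment: counts and frequencies of each direction, eligibility and
#'   calls), `gained` and `lost` (called subsets), `by_chromosome`
#'   (data.frame of gain/loss call counts per chromosome), `diffs` (the
#'   segments x pairs difference matrix), `config`.
#' @export
recurrent_differences <- function(tumor, xenograft, pairs,
                                  segments = NULL,
                                  config = recurrence_config(),
                                  clone_map = NULL) {
  if (nrow(pairs) < 1L) stop("need at least one pair")
  if (!inherits(config, "recurrence_config"))
    stop("config must be a recurrence_config")
  if (is.null(segments)) {
    if (is.null(clone_map))
      stop("supply either segments or a clone_map to derive them")
    segments <- define_segments(cbind(tumor, xenograft), clone_map)
  }
  diffs <- gnl_difference_matrix(tumor, xenograft, pairs, segments)
  n_present <- rowSums(!is.na(diffs))
  n_pos <- rowSums(diffs > 0, na.rm = TRUE)
  n_neg <- rowSums(diffs < 0, na.rm = TRUE)
  eligible <- n_present >= config$min_comparisons
  freq_pos <- ifelse(n_present > 0, n_pos / n_present, NA_real_)
  freq_neg <- ifelse(n_present > 0, n_neg / n_present, NA_real_)
  called_gain <- eligible & !is.na(freq_pos) &
    freq_pos >= config$min_pair_fraction
  called_loss <- eligible & !is.na(freq_neg) &
    freq_neg >= config$min_pair_fraction
  report <- cbind(as.data.frame(segments),
                  data.frame(n_present = as.integer(n_present),
                             n_pos = as.integer(n_pos),
                             n_neg = as.integer(n_neg),
                             freq_pos = freq_pos, freq_neg = freq_neg,
                             eligible = eligible,
                             called_gain = called_gain,
                             called_loss = called_loss))
  rownames(report) <- NULL
  chroms <- unique(segments$chrom)
  by_chrom <- data.frame(
    chrom = chroms,
    n_gained = vapply(chroms, function(ch)
      sum(called_gain[segments$chrom == ch]), integer(1)),
    n_lost = vapply(chroms, function(ch)
      sum(called_loss[segments$chrom == ch]), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- list(report = report,
              gained = report[report$called_gain, , drop = FALSE],
              lost = report[report$called_loss, , drop = FALSE],
              by_chromosome = by_chrom, diffs = diffs, config = config)
  class(out) <- "recurrent_region_report"
  out
}

#' @export
print.recurrent_region_report <- function(x, ...) {
  cat("recurrent GNL differences: ", nrow(x$report), " segments, ",
      sum(x$report$eligible), " eligible (>= ", x$config$min_comparisons,
      " comparisons); ", nrow(x$gained), " gained, ", nrow(x$lost),
      " lost at >= ", round(100 * x$config$min_pair_fraction), "% of pairs\n",
      sep = "")
  invisible(x)
}
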
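#' Status thresholds for log2-ratio discretization
#'
#' A simple threshold caller converting clone-level log2 ratios into
#' gain/normal/loss/amplification (GNL) status.  This is plumbing: a
#' declared stand-in for likelihood-based segmentation callers such as
#' GLAD, useful for simulated ratios and for quick looks at real ones.
#' The defaults (+/-0.25 for single-copy changes, +1.0 for amplification)
#' are configuration, not doctrine.
#'
#' @param loss_below call loss when log2 ratio `<=` this value.
#' @param gain_above call gain when log2 ratio `>=` this value.
#' @param amp_above call amplification when log2 ratio `>=` this value.
#' @return A list of class `status_thresholds`.
#' @export
status_thresholds <- function(loss_below = -0.25, gain_above = 0.25,
                              amp_above = 1.0) {
  if (!(loss_below < gain_above && gain_above < amp_above))
    stop("require loss_below < gain_above < amp_above")
  structure(list(loss_below = loss_below, gain_above = gain_above,
                 amp_above = amp_above),
            class = "status_thresholds")
}

#' Assign GNL status from log2 ratios
#'
#' Maps each clone's log2 ratio to an integer status code: loss (-1),
#' normal (0), gain (+1), amplification (+2); `NA` stays `NA`.  Boundaries
#' are inclusive on the altered side: a ratio exactly at `gain_above` is
#' called gain.
#'
#' @param ratios numeric vector or clones-x-samples matrix of log2 ratios
#'   (`NA` = missing).
#' @param thresholds a [status_thresholds()] object.
#' @return Integer vector or matrix of the same shape with values in
#'   \{-1, 0, 1, 2, NA\}.
#' @examples
#' assign_status(c(-0.5, 0, 0.25, 1.5, NA))
#' @export
assign_status <- function(ratios, thresholds = status_thresholds()) {
  if (!inherits(thresholds, "status_thresholds"))
    stop("thresholds must be a status_thresholds object")
  out <- ifelse(is.na(ratios), NA_integer_,
         ifelse(ratios <= thresholds$loss_below, -1L,
         ifelse(ratios >= thresholds$amp_above, 2L,
         ifelse(ratios >= thresholds$gain_above, 1L, 0L))))
  if (is.matrix(ratios)) {
    out <- matrix(as.integer(out), nrow = nrow(ratios),
                  dimnames = dimnames(ratios))
  } else {
    out <- as.integer(out)
    names(out) <- names(ratios)
  }
  out
}

#' Collapse amplification into gain
#'
#' Reduces the 4-level status encoding (loss/normal/gain/amplification) to
#' the 3-level GNL encoding (gain, normal, loss) used for pairwise
#' correlation and segmentation: amplification (+2) becomes gain (+1);
#' every other code, including missing, is unchanged.
#'
#' @param status integer vector or matrix of status codes.
#' @return Same shape, with no +2 values remaining.
#' @export
collapse_amplification <- function(status) {
  check_status_codes(status)
  status[!is.na(status) & status == 2L] <- 1L
  status
}

check_status_codes <- function(status) {
  vals <- status[!is.na(status)]
  if (length(vals) && !all(vals %in% c(-1L, 0L, 1L, 2L)))
    stop("status codes must be in {-1, 0, 1, 2} or NA")
  invisible(status)
}

#' Cohort gain/loss/amplification frequency track
#'
#' Per-clone frequency of each altered state across a cohort, computed
#' over informative (non-missing) calls only.  This is the quantity
#' plotted in genome-wide alteration-frequency tracks (FrAGL plots).
#'
#' @param profiles integer matrix of status codes, clones x samples
#'   (4-level codes allowed; amplification is counted separately from
#'   gain, so `freq_gain + freq_amp` is the total gained fraction).
#' @param clone_map optional [clone_map()] to validate against and to
#'   carry coordinates into the result.
#' @return A `data.frame` with one row per clone: `freq_gain`,
#'   `freq_loss`, `freq_amp`, `n_informative`.  Clones missing in every
#'   sample get `NA` frequencies.
#' @export
cna_frequency <- function(profiles, clone_map = NULL) {
  profiles <- check_profiles(profiles, clone_map)
  if (ncol(profiles) < 1L) stop("need at least one profile")
  check_status_codes(profiles)
  inf <- rowSums(!is.na(profiles))
  fg <- rowSums(profiles == 1L, na.rm = TRUE) / inf
  fl <- rowSums(profiles == -1L, na.rm = TRUE) / inf
  fa <- rowSums(profiles == 2L, na.rm = TRUE) / inf
  none <- inf == 0L
  fg[none] <- fl[none] <- fa[none] <- NA_real_
  out <- data.frame(clone_id = rownames(profiles) %||%
                      sprintf("clone%0*d", nchar(nrow(profiles)), seq_len(nrow(profiles))),
                    freq_gain = fg, freq_loss = fl, freq_amp = fa,
                    n_informative = as.integer(inf),
                    stringsAsFactors = FALSE)
  if (!is.null(clone_map)) {
    out$chrom <- clone_map$chrom
    out$start <- clone_map$start
    out$end <- clone_map$end
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
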
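#' Construct a clone map
#'
#' A clone map is the ordered genomic grid shared by every profile in a
#' cohort: one row per BAC/PAC clone (or any fixed measurement locus), with
#' a unique identifier and 1-based inclusive base-pair coordinates.  All
#' status and ratio profiles in an analysis are vectors over this grid, in
#' this order.
#'
#' @param clone_id character vector of unique clone identifiers.
#' @param chrom chromosome label per clone (e.g. `"chr1"`, `"chrX"`).
#' @param start,end integer base-pair positions, 1-based inclusive,
#'   `end >= start`.
#' @param sort sort rows by (chromosome, start)? Chromosomes are ordered
#'   naturally (chr1, chr2, ..., chr10, ..., chrX). Default `TRUE`.
#' @return A `data.frame` of class `clone_map` with columns `clone_id`,
#'   `chrom`, `start`, `end`, sorted by genomic position.
#' @examples
#' clone_map(c("c1", "c2"), c("chr1", "chr1"), c(1, 1001), c(1000, 2000))
#' @export
clone_map <- function(clone_id, chrom, start, end, sort = TRUE) {
  clone_id <- as.character(clone_id)
  chrom <- as.character(chrom)
  start <- as.integer(start)
  end <- as.integer(end)
  n <- length(clone_id)
  if (length(chrom) != n || length(start) != n || length(end) != n)
    stop("clone_id, chrom, start, end must have equal length")
  if (anyDuplicated(clone_id))
    stop("duplicate clone_id: ", clone_id[duplicated(clone_id)][1L])
  if (any(is.na(start)) || any(is.na(end)) || any(end < start))
    stop("coordinates must be non-missing with end >= start")
  if (any(start < 1L)) stop("coordinates are 1-based; start must be >= 1")
  cm <- data.frame(clone_id = clone_id, chrom = chrom,
                   start = start, end = end, stringsAsFactors = FALSE)
  if (sort) {
    ord <- order(chrom_rank(cm$chrom), cm$start, cm$end)
    cm <- cm[ord, , drop = FALSE]
  } else {
    if (is.unsorted(order(chrom_rank(cm$chrom), cm$start)))
      stop("clone map rows are not sorted by (chromosome, start)")
  }
  rownames(cm) <- NULL
  class(cm) <- c("clone_map", "data.frame")
  cm
}

# Natural chromosome order: numeric part if present (chr1 < chr2 < chr10),
# non-numeric labels (X, Y, MT, ...) after, alphabetically.
chrom_rank <- function(chrom) {
  stripped <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.numeric(stripped))
  lev <- unique(chrom)
  slev <- sub("^chr", "", lev)
  nlev <- suppressWarnings(as.numeric(slev))
  ord <- order(is.na(nlev), nlev, slev)
  match(chrom, lev[ord]) + ifelse(is.na(num), 0, 0)
}

#' @export
print.clone_map <- function(x, ...) {
  cat("clone map: ", nrow(x), " clones on ",
      length(unique(x$chrom)), " chromosome(s)\n", sep = "")
  NextMethod()
}

is_clone_map <- function(x) inherits(x, "clone_map")

stopifnot_clone_map <- function(x) {
  if (!is_clone_map(x)) stop("expected a clone_map object")
  invisible(x)
}

# Check a profile matrix (clones x samples) against a clone map.
check_profiles <- function(profiles, clone_map = NULL) {
  if (is.null(dim(profiles)))
    profiles <- matrix(profiles, ncol = 1L,
                       dimnames = list(names(profiles), "sample"))
  if (!is.null(clone_map)) {
    stopifnot_clone_map(clone_map)
    if (nrow(profiles) != nrow(clone_map))
      stop("profile length (", nrow(profiles),
           ") does not match clone map (", nrow(clone_map), ")")
    if (!is.null(rownames(profiles)) &&
        !identical(rownames(profiles), clone_map$clone_id))
      stop("profile row names do not match clone map clone_ids (same order required)")
  }
  profiles
}
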
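#' Read a clone map TSV
#'
#' Expects tab-separated columns `clone_id`, `chrom`, `start`, `end` with
#' a header; coordinates are 1-based inclusive and preserved as such.
#'
#' @param path file path.
#' @return A [clone_map()].
#' @export
read_clone_map <- function(path) {
  df <- read_tsv_checked(path, c("clone_id", "chrom", "start", "end"))
  clone_map(df$clone_id, df$chrom, df$start, df$end)
}

#' Write a clone map TSV
#' @param x a [clone_map()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_clone_map <- function(x, path) {
  stopifnot_clone_map(x)
  write_tsv(as.data.frame(x), path)
}

# shared TSV plumbing -------------------------------------------------------

read_tsv_checked <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "",
                            comment.char = "")
  if (length(nf) == 0L) stop(path, ": file is empty")
  bad <- which(nf != nf[1])
  if (length(bad))
    stop(path, ": line ", bad[1] + 0L, " has ", nf[bad[1]],
         " fields, expected ", nf[1])
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a clones-x-samples profile matrix TSV
#'
#' First column = clone ids (header `clone_id`), remaining columns one
#' per sample; cells are integer status codes in \{-1, 0, 1, 2\} (`mode
#' = "status"`), or real log2 ratios (`mode = "ratio"`); `NA` or empty =
#' missing.
#'
#' @param path file path.
#' @param mode `"status"` or `"ratio"`.
#' @param clone_map optional [clone_map()] to validate clone ids/order
#'   against.
#' @return Numeric (or integer) matrix with clone rownames.
#' @export
read_profile_matrix <- function(path, mode = c("status", "ratio"),
                                clone_map = NULL) {
  mode <- match.arg(mode)
  df <- read_tsv_checked(path, "clone_id")
  if (anyDuplicated(df$clone_id))
    stop(path, ": duplicate clone_id ", df$clone_id[duplicated(df$clone_id)][1])
  m <- as.matrix(df[, setdiff(names(df), "clone_id"), drop = FALSE])
  rownames(m) <- df$clone_id
  if (mode == "status") {
    storage.mode(m) <- "integer"
    check_status_codes(m)
  } else {
    storage.mode(m) <- "double"
  }
  if (!is.null(clone_map)) check_profiles(m, clone_map)
  m
}

#' Write a profile matrix TSV
#' @param m matrix with clone rownames.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(m, path) {
  df <- data.frame(clone_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read an expression matrix TSV
#'
#' First column `probe_id`, remaining columns one per sample, log2
#' values.
#'
#' @param path file path.
#' @return Numeric matrix with probe rownames.
#' @export
read_expression <- function(path) {
  df <- read_tsv_checked(path, "probe_id")
  if (anyDuplicated(df$probe_id))
    stop(path, ": duplicate probe_id ", df$probe_id[duplicated(df$probe_id)][1])
  m <- as.matrix(df[, setdiff(names(df), "probe_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$probe_id
  m
}

#' Write an expression matrix TSV
#' @param m numeric matrix with probe rownames.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a subtype centroid table TSV
#'
#' Rows = genes (first column `gene_id`), columns = subtypes.
#'
#' @param path file path.
#' @return Numeric genes x subtypes matrix.
#' @export
read_centroids <- function(path) {
  df <- read_tsv_checked(path, "gene_id")
  if (anyDuplicated(df$gene_id))
    stop(path, ": duplicate gene_id ", df$gene_id[duplicated(df$gene_id)][1])
  m <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene_id
  if (ncol(m) < 2L) stop(path, ": need at least two subtype columns")
  m
}

#' Write a centroid table TSV
#' @param m numeric genes x subtypes matrix.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_centroids <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.  Set names must be unique; empty sets are an
#' error.
#'
#' @param path file path.
#' @return Named list of character vectors; descriptions in attribute
#'   `"description"`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(path, ": file is empty")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop(path, ": line ", short[1], " has fewer than 3 fields")
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop(path, ": duplicate set name ", nms[duplicated(nms)][1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nms
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2L)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path file path.
#' @param description per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Export a segment table as BED
#'
#' Converts the 1-based inclusive segment coordinates to BED's 0-based
#' half-open convention (`bed_start = start - 1`, `bed_end = end`).
#'
#' @param segments a `segment_table` from [define_segments()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start - 1L,
                    end = segments$end,
                    name = segments$segment_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a dendrogram as Newick
#'
#' Exports an `hclust` tree (e.g. from [cluster_profiles()]) as a rooted
#' Newick string via `ape`, with branch lengths derived from the merge
#' heights.  Leaf labels are sanitized: characters Newick reserves
#' (colons, parentheses, commas, semicolons, whitespace) become `_`.
#'
#' @param hc an `hclust` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(hc, path) {
  if (!inherits(hc, "hclust")) stop("hc must be an hclust tree")
  lab <- gsub("[:;,()\\s\\[\\]]", "_", hc$labels, perl = TRUE)
  if (length(lab) == 1L) {
    writeLines(paste0(lab, ";"), path)
    return(invisible(path))
  }
  hc$labels <- lab
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
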
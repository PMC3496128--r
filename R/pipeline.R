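#' Pipeline configuration
#'
#' Collects every stage parameter of the tumor/xenograft concordance
#' pipeline with its standard default, plus input locations and the
#' output directory.  Unknown parameter names are rejected.
#'
#' Inputs may be file paths (TSV/GMT, see the `read_*` readers) or
#' in-memory objects of the matching type; any omitted input disables
#' the stages that need it, except the copy-number and expression
#' cohorts, which are simulated from the packaged generators when
#' omitted (so the default configuration runs end to end).
#'
#' @param cna `NULL` (simulate via [gen_paired_cna()]) or a list with
#'   `clone_map`, `tumor`, `xenograft` (status matrices or paths; or
#'   `ratio = TRUE` to threshold-call real-valued matrices) and `pairs`.
#' @param expr `NULL` (simulate via [gen_paired_expression()]) or a list
#'   with `tumor`, `xenograft` matrices/paths (probes x pairs, matched
#'   column order).
#' @param centroids optional centroid matrix or TSV path; enables the
#'   subtyping stage.
#' @param id_map optional data.frame (`gene_id`, `probe_id`) or TSV path
#'   mapping centroid genes to expression probes; `NULL` means centroid
#'   rownames are probe ids.
#' @param gene_sets optional GMT path or named list; enables enrichment.
#' @param thresholds [status_thresholds()] for ratio calling.
#' @param recurrence [recurrence_config()] for recurrent differences.
#' @param filter_floor,filter_max_below probe filter parameters
#'   (defaults 3.5 and 0.85).
#' @param lo_pct,hi_pct residual percentile bounds (defaults 5, 95).
#' @param min_corr subtype unclassified threshold (default 0.2).
#' @param high_k recurrence level at/above which probes form the
#'   enrichment gene list (default 10).
#' @param seed integer seed used for any simulated inputs.
#' @param out_dir output directory (created if needed).
#' @return A list of class `run_config`.
#' @export
run_config <- function(cna = NULL, expr = NULL, centroids = NULL,
                       id_map = NULL, gene_sets = NULL,
                       thresholds = status_thresholds(),
                       recurrence = recurrence_config(),
                       filter_floor = 3.5, filter_max_below = 0.85,
                       lo_pct = 5, hi_pct = 95, min_corr = 0.2,
                       high_k = 10L, seed = 1L, out_dir = tempfile("pdx")) {
  structure(list(cna = cna, expr = expr, centroids = centroids,
                 id_map = id_map, gene_sets = gene_sets,
                 thresholds = thresholds,
                 recurrence = recurrence, filter_floor = filter_floor,
                 filter_max_below = filter_max_below, lo_pct = lo_pct,
                 hi_pct = hi_pct, min_corr = min_corr,
                 high_k = as.integer(high_k), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

load_matrix <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1L) reader(x, ...) else x
}

#' Run the tumor/xenograft concordance pipeline end to end
#'
#' Orchestrates: status assignment (when ratio inputs are given),
#' per-pair GNL concordance, cohort clustering and pair co-segregation,
#' constant-status segmentation, recurrent GNL-difference calling,
#' cohort frequency tracks, probe filtering, per-pair residual outlier
#' calling, cross-pair recurrence with the direction chi-square trend,
#' nearest-centroid subtyping (when centroids are supplied) and gene-set
#' enrichment of highly recurrent probes (when gene sets are supplied).
#' Every stage's table is written under `config$out_dir` along with a
#' JSON manifest recording parameters, seed and outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with every stage result plus `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(writer, obj, name) {
    p <- file.path(config$out_dir, name)
    writer(obj, p)
    outputs[[length(outputs) + 1L]] <<- name
  }

  # ---- copy-number cohort ----
  cna <- stage("cna-input", {
    if (is.null(config$cna)) {
      gen_paired_cna(cna_sim_config(seed = config$seed))
    } else {
      x <- config$cna
      cm <- if (is.character(x$clone_map)) read_clone_map(x$clone_map)
            else x$clone_map
      mode <- if (isTRUE(x$ratio)) "ratio" else "status"
      tum <- load_matrix(x$tumor, read_profile_matrix, mode = mode,
                         clone_map = cm)
      xen <- load_matrix(x$xenograft, read_profile_matrix, mode = mode,
                         clone_map = cm)
      if (isTRUE(x$ratio)) {
        tum <- assign_status(tum, config$thresholds)
        xen <- assign_status(xen, config$thresholds)
      }
      prs <- if (is.character(x$pairs))
        read_tsv_checked(x$pairs, c("pair_id", "tumor", "xenograft"))
      else x$pairs
      list(clone_map = cm, tumor = tum, xenograft = xen, pairs = prs)
    }
  })

  conc <- stage("cna-concordance",
                concordance_table(cna$tumor, cna$xenograft, cna$pairs))
  emit(write_tsv, conc, "concordance.tsv")

  clus <- stage("cna-cluster", {
    all_prof <- cbind(cna$tumor, cna$xenograft)
    hc <- cluster_profiles(correlation_distance_matrix(all_prof))
    n_coseg <- count_cosegregating_pairs(hc, cna$pairs)
    list(hclust = hc, n_cosegregating = as.integer(n_coseg),
         cosegregating = attr(n_coseg, "cosegregating"))
  })
  emit(write_dendrogram, clus$hclust, "dendrogram.nwk")

  freq <- stage("cna-frequency", list(
    tumor = cna_frequency(cna$tumor, cna$clone_map),
    xenograft = cna_frequency(cna$xenograft, cna$clone_map)))
  emit(write_tsv, freq$tumor, "frequency_tumor.tsv")
  emit(write_tsv, freq$xenograft, "frequency_xenograft.tsv")

  segs <- stage("cna-segments",
                define_segments(cbind(cna$tumor, cna$xenograft),
                                cna$clone_map))
  emit(write_tsv, as.data.frame(segs), "segments.tsv")
  emit(write_segments_bed, segs, "segments.bed")

  recur <- stage("cna-recurrent-differences", {
    if (config$recurrence$min_comparisons > nrow(cna$pairs))
      warning("min_comparisons (", config$recurrence$min_comparisons,
              ") exceeds the number of pairs (", nrow(cna$pairs),
              "); no segment can be eligible", call. = FALSE)
    recurrent_differences(cna$tumor, cna$xenograft, cna$pairs,
                          segments = segs, config = config$recurrence)
  })
  emit(write_tsv, recur$report, "recurrent_regions.tsv")
  emit(function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE,
                                           digits = NA),
       list(by_chromosome = recur$by_chromosome,
            n_gained = nrow(recur$gained), n_lost = nrow(recur$lost)),
       "recurrent_summary.json")

  # ---- expression cohort ----
  expr <- stage("expr-input", {
    if (is.null(config$expr)) {
      gen_paired_expression(expr_sim_config(seed = config$seed))
    } else {
      list(tumor = load_matrix(config$expr$tumor, read_expression),
           xenograft = load_matrix(config$expr$xenograft, read_expression))
    }
  })

  filt <- stage("expr-filter",
                filter_probesets(cbind(expr$tumor, expr$xenograft),
                                 floor = config$filter_floor,
                                 max_below_fraction = config$filter_max_below))
  keep <- filt$kept

  de <- stage("expr-de", {
    lapply(seq_len(ncol(expr$tumor)), function(j)
      paired_outliers(expr$tumor[keep, j], expr$xenograft[keep, j],
                      lo_pct = config$lo_pct, hi_pct = config$hi_pct,
                      pair_id = colnames(expr$tumor)[j] %||%
                        paste0("pair", j)))
  })
  de_tab <- do.call(rbind, lapply(de, function(r)
    data.frame(pair_id = r$pair_id,
               probe = c(r$over_probes, r$under_probes),
               direction = rep(c("over", "under"),
                               c(length(r$over_probes),
                                 length(r$under_probes))),
               residual = r$residuals[c(r$over_probes, r$under_probes)],
               stringsAsFactors = FALSE)))
  emit(write_tsv, de_tab, "pair_outliers.tsv")

  rec_tab <- stage("expr-recurrence", recurrence_table(de, universe = keep))
  emit(write_tsv, rec_tab$table, "recurrence_table.tsv")

  chisq <- stage("expr-direction-trend", {
    n_pairs <- length(de)
    hi <- min(config$high_k, n_pairs)
    tryCatch(direction_trend_chisq(rec_tab, 1L, hi:n_pairs),
             error = function(e) NULL)
  })
  if (!is.null(chisq))
    emit(function(o, p) jsonlite::write_json(
           list(statistic = o$statistic, p_value = o$p_value, df = o$df),
           p, auto_unbox = TRUE, digits = NA),
         chisq, "direction_trend.json")

  # ---- subtyping ----
  subtype <- NULL
  if (!is.null(config$centroids)) {
    subtype <- stage("subtype", {
      cen <- if (is.character(config$centroids))
        read_centroids(config$centroids) else config$centroids
      im <- if (is.character(config$id_map))
        read_tsv_checked(config$id_map, c("gene_id", "probe_id"))
      else config$id_map
      m <- match_genes(cen, cbind(expr$tumor, expr$xenograft),
                       id_map = im)
      classify_samples(m$matrix, m$centroids, min_corr = config$min_corr)
    })
    emit(write_tsv, subtype, "subtype_calls.tsv")
  }

  # ---- enrichment ----
  enrichment <- NULL
  if (!is.null(config$gene_sets)) {
    enrichment <- stage("enrichment", {
      sets <- if (is.character(config$gene_sets))
        read_gmt(config$gene_sets) else config$gene_sets
      hits <- rec_tab$per_probe$probe[rec_tab$per_probe$k >= config$high_k]
      if (length(hits) == 0L) NULL else enrich(hits, keep, sets)
    })
    if (!is.null(enrichment)) emit(write_tsv, enrichment, "enrichment.tsv")
  }

  manifest <- list(
    package = "pdxconcord",
    version = as.character(utils::packageVersion("pdxconcord")),
    seed = config$seed,
    parameters = list(
      thresholds = unclass(config$thresholds),
      recurrence = unclass(config$recurrence),
      filter = list(floor = config$filter_floor,
                    max_below_fraction = config$filter_max_below),
      percentiles = c(lo = config$lo_pct, hi = config$hi_pct),
      min_corr = config$min_corr, high_k = config$high_k),
    n_pairs_cna = nrow(cna$pairs),
    n_clones = nrow(cna$clone_map),
    n_segments = nrow(segs),
    n_cosegregating = clus$n_cosegregating,
    probes_kept = filt$n_kept, probes_removed = filt$n_removed,
    outputs = unlist(outputs))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cna = cna, concordance = conc, clustering = clus,
                 frequency = freq, segments = segs, recurrent = recur,
                 expression = expr, filter = filt, de = de,
                 recurrence = rec_tab, direction_trend = chisq,
                 subtype = subtype, enrichment = enrichment,
                 manifest = manifest))
}
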
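#' Configuration for the paired copy-number simulator
#'
#' Defines a paired tumor/xenograft aCGH-style cohort: a fixed clone grid,
#' copy-number events planted in each tumor, a fraction of those events
#' retained in the derived xenograft, xenograft-private events, optional
#' recurrent xenograft-private segments shared across a fraction of pairs,
#' and independent per-spot missingness.  Defaults describe a cohort of 20
#' tumor/xenograft pairs measured on 2,000 clones (20 chromosomes x 100
#' clones), the scale of BAC-array breast cancer cohorts.
#'
#' @param n_pairs number of tumor/xenograft pairs.
#' @param n_chromosomes,clones_per_chromosome grid dimensions.
#' @param n_events_per_tumor copy-number events planted per tumor.
#' @param event_length length-2 integer range (in clones) of planted events.
#' @param shared_fraction probability a tumor event is retained in the
#'   xenograft.
#' @param private_event_rate expected number (Poisson) of xenograft-only
#'   events per pair.
#' @param recurrent_private_segments list of recurrent xenograft-private
#'   alterations, each a list with elements `chrom` (chromosome index),
#'   `from`, `to` (clone indices within the chromosome), `sign` (-1 or +1)
#'   and `carrier_fraction` (probability a pair carries it).
#' @param missing_rate probability each clone call (independently per
#'   sample) is missing.
#' @param seed integer RNG seed.
#' @return A validated list of class `cna_sim_config`.
#' @export
cna_sim_config <- function(n_pairs = 20L,
                           n_chromosomes = 20L,
                           clones_per_chromosome = 100L,
                           n_events_per_tumor = 8L,
                           event_length = c(5L, 40L),
                           shared_fraction = 0.85,
                           private_event_rate = 2,
                           recurrent_private_segments = list(),
                           missing_rate = 0.1,
                           seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs),
              n_chromosomes = as.integer(n_chromosomes),
              clones_per_chromosome = as.integer(clones_per_chromosome),
              n_events_per_tumor = as.integer(n_events_per_tumor),
              event_length = as.integer(event_length),
              shared_fraction = shared_fraction,
              private_event_rate = private_event_rate,
              recurrent_private_segments = recurrent_private_segments,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_pairs >= 1L, n_chromosomes >= 1L,
              clones_per_chromosome >= 1L, n_events_per_tumor >= 0L,
              length(event_length) == 2L, event_length[1] >= 1L,
              event_length[1] <= event_length[2])
    if (event_length[2] > clones_per_chromosome)
      stop("event_length exceeds chromosome size (",
           clones_per_chromosome, " clones)")
    for (p in c(shared_fraction, missing_rate))
      if (is.na(p) || p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
    if (private_event_rate < 0) stop("private_event_rate must be >= 0")
  })
  for (seg in cfg$recurrent_private_segments) {
    stopifnot(is.list(seg),
              all(c("chrom", "from", "to", "sign", "carrier_fraction")
                  %in% names(seg)))
    if (seg$chrom < 1L || seg$chrom > cfg$n_chromosomes)
      stop("recurrent segment chromosome out of range")
    if (seg$from < 1L || seg$to > cfg$clones_per_chromosome ||
        seg$from > seg$to)
      stop("recurrent segment clone range invalid")
    if (!seg$sign %in% c(-1L, 1L)) stop("recurrent segment sign must be -1 or +1")
    if (seg$carrier_fraction < 0 || seg$carrier_fraction > 1)
      stop("carrier_fraction must lie in [0, 1]")
  }
  structure(cfg, class = "cna_sim_config")
}

# Sample a non-overlapping event (chrom, from, to) for one profile.
# occupied: list per chromosome of a logical clone mask.
sample_event <- function(cfg, occupied, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    chrom <- sample.int(cfg$n_chromosomes, 1L)
    len <- sample(seq(cfg$event_length[1], cfg$event_length[2]), 1L)
    from <- sample.int(cfg$clones_per_chromosome - len + 1L, 1L)
    to <- from + len - 1L
    if (!any(occupied[[chrom]][from:to]))
      return(list(chrom = chrom, from = from, to = to))
  }
  stop("could not place a non-overlapping event in 100 attempts; ",
       "reduce event number/length or enlarge the genome")
}

#' Simulate a paired tumor/xenograft copy-number cohort
#'
#' Generates tumor status profiles with planted gain/loss events, then
#' derives each xenograft by retaining each tumor event with probability
#' `shared_fraction`, adding Poisson-distributed private events
#' (sign-symmetric), applying any configured recurrent private segments to
#' a random subset of carrier pairs, and finally masking calls as missing
#' independently per clone per sample.  Events within a sample never
#' overlap; the full ground truth is returned.
#'
#' @param config a [cna_sim_config()].
#' @return A list with elements `clone_map` ([clone_map()]), `tumor` and
#'   `xenograft` (integer status matrices, clones x pairs), `pairs`
#'   (data.frame `pair_id`, `tumor`, `xenograft` sample ids) and `truth`
#'   (planted/retained/private events and recurrent-segment carriers).
#' @examples
#' sim <- gen_paired_cna(cna_sim_config(n_pairs = 4, n_chromosomes = 3,
#'   clones_per_chromosome = 30, n_events_per_tumor = 2,
#'   event_length = c(3, 8), missing_rate = 0, seed = 7))
#' dim(sim$tumor)
#' @export
gen_paired_cna <- function(config = cna_sim_config()) {
  if (!inherits(config, "cna_sim_config"))
    stop("config must be a cna_sim_config")
  cfg <- config
  set.seed(cfg$seed)
  n_clones <- cfg$n_chromosomes * cfg$clones_per_chromosome
  # 1 Mb clones laid end to end, matching BAC-grid resolution
  cm <- clone_map(
    clone_id = sprintf("c%02d_%04d",
                       rep(seq_len(cfg$n_chromosomes),
                           each = cfg$clones_per_chromosome),
                       rep(seq_len(cfg$clones_per_chromosome),
                           cfg$n_chromosomes)),
    chrom = sprintf("chr%d", rep(seq_len(cfg$n_chromosomes),
                                 each = cfg$clones_per_chromosome)),
    start = rep((seq_len(cfg$clones_per_chromosome) - 1L) * 1000000L + 1L,
                cfg$n_chromosomes),
    end = rep(seq_len(cfg$clones_per_chromosome) * 1000000L,
              cfg$n_chromosomes))
  offset <- (seq_len(cfg$n_chromosomes) - 1L) * cfg$clones_per_chromosome

  pair_ids <- sprintf("P%02d", seq_len(cfg$n_pairs))
  tumor_ids <- paste0(pair_ids, "_T")
  xeno_ids <- paste0(pair_ids, "_X")
  tumor <- matrix(0L, n_clones, cfg$n_pairs,
                  dimnames = list(cm$clone_id, tumor_ids))
  xeno <- matrix(0L, n_clones, cfg$n_pairs,
                 dimnames = list(cm$clone_id, xeno_ids))

  tumor_events <- list()
  retained <- list()
  private <- list()

  # recurrent private segments: decide carriers up front
  rec_truth <- list()
  rec_mask <- vector("list", cfg$n_pairs)  # per-pair occupied mask additions
  for (k in seq_along(cfg$recurrent_private_segments)) {
    seg <- cfg$recurrent_private_segments[[k]]
    carriers <- which(stats::runif(cfg$n_pairs) < seg$carrier_fraction)
    rec_truth[[k]] <- list(chrom = seg$chrom, from = seg$from, to = seg$to,
                           sign = as.integer(seg$sign),
                           carrier_fraction = seg$carrier_fraction,
                           carriers = pair_ids[carriers])
  }

  for (j in seq_len(cfg$n_pairs)) {
    occupied <- replicate(cfg$n_chromosomes,
                          logical(cfg$clones_per_chromosome),
                          simplify = FALSE)
    # reserve recurrent-segment footprints so tumor events never overlap them
    for (k in seq_along(rec_truth)) {
      r <- rec_truth[[k]]
      occupied[[r$chrom]][r$from:r$to] <- TRUE
    }
    ev_list <- list()
    for (e in seq_len(cfg$n_events_per_tumor)) {
      ev <- sample_event(cfg, occupied)
      occupied[[ev$chrom]][ev$from:ev$to] <- TRUE
      ev$sign <- sample(c(-1L, 1L), 1L)
      idx <- offset[ev$chrom] + ev$from:ev$to
      tumor[idx, j] <- ev$sign
      ev$pair_id <- pair_ids[j]
      ev_list[[e]] <- ev
    }
    tumor_events[[j]] <- ev_list

    # xenograft inherits retained events
    keep <- stats::runif(length(ev_list)) < cfg$shared_fraction
    retained[[j]] <- ev_list[keep]
    for (ev in ev_list[keep]) {
      idx <- offset[ev$chrom] + ev$from:ev$to
      xeno[idx, j] <- ev$sign
    }
    # private xenograft-only events, non-overlapping with everything placed
    n_priv <- stats::rpois(1L, cfg$private_event_rate)
    priv_list <- list()
    for (e in seq_len(n_priv)) {
      ev <- sample_event(cfg, occupied)
      occupied[[ev$chrom]][ev$from:ev$to] <- TRUE
      ev$sign <- sample(c(-1L, 1L), 1L)
      idx <- offset[ev$chrom] + ev$from:ev$to
      xeno[idx, j] <- ev$sign
      ev$pair_id <- pair_ids[j]
      priv_list[[e]] <- ev
    }
    private[[j]] <- priv_list

    # recurrent private segments for carrier pairs
    for (k in seq_along(rec_truth)) {
      r <- rec_truth[[k]]
      if (pair_ids[j] %in% r$carriers) {
        idx <- offset[r$chrom] + r$from:r$to
        xeno[idx, j] <- r$sign
      }
    }
  }

  if (cfg$missing_rate > 0) {
    tumor[stats::runif(length(tumor)) < cfg$missing_rate] <- NA_integer_
    xeno[stats::runif(length(xeno)) < cfg$missing_rate] <- NA_integer_
  }

  truth <- list(tumor_events = do.call(rbind, lapply(unlist(tumor_events,
                  recursive = FALSE), as.data.frame)),
                retained_events = do.call(rbind, lapply(unlist(retained,
                  recursive = FALSE), as.data.frame)),
                private_events = do.call(rbind, lapply(unlist(private,
                  recursive = FALSE), as.data.frame)),
                recurrent_segments = rec_truth)
  list(clone_map = cm, tumor = tumor, xenograft = xeno,
       pairs = data.frame(pair_id = pair_ids, tumor = tumor_ids,
                          xenograft = xeno_ids, stringsAsFactors = FALSE),
       truth = truth)
}

#' Configuration for the paired expression simulator
#'
#' Defines a paired tumor/xenograft expression cohort on the
#' post-normalization log2 scale.  Each expressed probe has a baseline
#' level shared by the pair; the xenograft value equals the tumor value
#' plus a fixed negative shift on a designated "stromal" probe subset
#' (emulating loss of human stroma in the graft) plus residual noise.  A
#' fraction of probes is simulated below the detection floor in every
#' sample so the standard low-signal filter removes them.  Defaults
#' describe 13 pairs and 20,000 probes with 200 stromal probes shifted by
#' -2 log2 units.
#'
#' @param n_probes,n_pairs cohort dimensions.
#' @param baseline_mean,baseline_sd log2-signal distribution of expressed
#'   probes.
#' @param stromal_set_size number of stromal probes.
#' @param stromal_shift log2 change applied to stromal probes in
#'   xenografts (negative = down in xenograft).
#' @param noise_sd residual noise sd (log2), applied independently to the
#'   tumor-vs-baseline and xenograft-vs-tumor layers.
#' @param low_signal_fraction fraction of probes planted below the
#'   detection floor.
#' @param detection_floor log2 detection threshold (default 3.5).
#' @param seed integer RNG seed.
#' @return A validated list of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_probes = 20000L, n_pairs = 13L,
                            baseline_mean = 8, baseline_sd = 2,
                            stromal_set_size = 200L, stromal_shift = -2,
                            noise_sd = 0.5, low_signal_fraction = 0,
                            detection_floor = 3.5, seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes), n_pairs = as.integer(n_pairs),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              stromal_set_size = as.integer(stromal_set_size),
              stromal_shift = stromal_shift, noise_sd = noise_sd,
              low_signal_fraction = low_signal_fraction,
              detection_floor = detection_floor, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_probes >= 1L, n_pairs >= 1L, baseline_sd >= 0,
              noise_sd > 0, stromal_set_size >= 0L)
    if (stromal_set_size > n_probes)
      stop("stromal_set_size exceeds n_probes")
    if (low_signal_fraction < 0 || low_signal_fraction > 1)
      stop("low_signal_fraction must lie in [0, 1]")
    n_low <- round(low_signal_fraction * n_probes)
    if (stromal_set_size > n_probes - n_low)
      stop("not enough expressed probes for the stromal set")
  })
  structure(cfg, class = "expr_sim_config")
}

#' Simulate a paired tumor/xenograft expression cohort
#'
#' For each expressed probe, the tumor value in each pair is the probe
#' baseline plus noise; the xenograft value is the tumor value plus
#' `stromal_shift` (stromal probes only) plus independent noise.
#' Low-signal probes are drawn strictly below the detection floor in every
#' sample.  Expressed baselines are truncated above the floor so the
#' low-signal filter separates the two groups cleanly.
#'
#' @param config an [expr_sim_config()].
#' @return A list with `tumor` and `xenograft` matrices (probes x pairs,
#'   log2 scale), `samples` (annotation data.frame with `sample_id`,
#'   `pair_id`, `role`) and `truth` (`stromal_probes`, `low_probes`).
#' @export
gen_paired_expression <- function(config = expr_sim_config()) {
  if (!inherits(config, "expr_sim_config"))
    stop("config must be an expr_sim_config")
  cfg <- config
  set.seed(cfg$seed)
  probe_ids <- sprintf("probe%05d", seq_len(cfg$n_probes))
  pair_ids <- sprintf("P%02d", seq_len(cfg$n_pairs))

  n_low <- round(cfg$low_signal_fraction * cfg$n_probes)
  low_idx <- if (n_low > 0) sample.int(cfg$n_probes, n_low) else integer(0)
  expressed_idx <- setdiff(seq_len(cfg$n_probes), low_idx)
  stromal_idx <- if (cfg$stromal_set_size > 0)
    sample(expressed_idx, cfg$stromal_set_size) else integer(0)

  # expressed baselines: truncated normal, kept >= 1 above the floor
  base <- stats::rnorm(cfg$n_probes, cfg$baseline_mean, cfg$baseline_sd)
  base <- pmax(base, cfg$detection_floor + 1)

  tumor <- base + matrix(stats::rnorm(cfg$n_probes * cfg$n_pairs,
                                      sd = cfg$noise_sd),
                         cfg$n_probes, cfg$n_pairs)
  shift <- numeric(cfg$n_probes)
  shift[stromal_idx] <- cfg$stromal_shift
  xeno <- tumor + shift + matrix(stats::rnorm(cfg$n_probes * cfg$n_pairs,
                                              sd = cfg$noise_sd),
                                 cfg$n_probes, cfg$n_pairs)

  if (n_low > 0) {
    # below-floor signal in every sample, bounded away from the floor
    lo <- function(n) stats::runif(n, cfg$detection_floor - 2,
                                   cfg$detection_floor - 0.05)
    tumor[low_idx, ] <- lo(n_low * cfg$n_pairs)
    xeno[low_idx, ] <- lo(n_low * cfg$n_pairs)
  }

  dimnames(tumor) <- list(probe_ids, paste0(pair_ids, "_T"))
  dimnames(xeno) <- list(probe_ids, paste0(pair_ids, "_X"))
  samples <- data.frame(
    sample_id = c(colnames(tumor), colnames(xeno)),
    pair_id = rep(pair_ids, 2L),
    role = rep(c("tumor", "xenograft"), each = cfg$n_pairs),
    stringsAsFactors = FALSE)
  list(tumor = tumor, xenograft = xeno, samples = samples,
       truth = list(stromal_probes = probe_ids[sort(stromal_idx)],
                    low_probes = probe_ids[sort(low_idx)]))
}

#' Simulate a centroid-structured subtype cohort
#'
#' Draws subtype centroids (one expression value per gene per subtype)
#' and generates samples as their subtype centroid plus i.i.d. Gaussian
#' noise, with labels recorded, for validating nearest-centroid
#' classification.
#'
#' @param n_subtypes number of subtypes (>= 2).
#' @param n_genes genes per centroid.
#' @param n_samples_per_subtype samples drawn from each subtype.
#' @param noise_sd per-gene noise sd (centroids have unit spread).
#' @param seed integer RNG seed.
#' @return A list with `centroids` (genes x subtypes matrix), `expression`
#'   (genes x samples matrix) and `labels` (true subtype per sample).
#' @export
gen_centroid_cohort <- function(n_subtypes = 5L, n_genes = 306L,
                                n_samples_per_subtype = 10L,
                                noise_sd = 0.5, seed = 1L) {
  stopifnot(n_subtypes >= 2L, n_genes >= 2L, n_samples_per_subtype >= 1L,
            noise_sd >= 0)
  set.seed(as.integer(seed))
  genes <- sprintf("gene%04d", seq_len(n_genes))
  subtypes <- paste0("Subtype", LETTERS[seq_len(n_subtypes)])
  centroids <- matrix(stats::rnorm(n_genes * n_subtypes), n_genes,
                      n_subtypes, dimnames = list(genes, subtypes))
  n_samples <- n_subtypes * n_samples_per_subtype
  labels <- rep(subtypes, each = n_samples_per_subtype)
  expr <- centroids[, rep(seq_len(n_subtypes),
                          each = n_samples_per_subtype), drop = FALSE] +
    matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
           n_genes, n_samples)
  colnames(expr) <- sprintf("S%03d", seq_len(n_samples))
  names(labels) <- colnames(expr)
  list(centroids = centroids, expression = expr, labels = labels)
}
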
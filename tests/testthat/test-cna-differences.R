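# small helper: clone map with one or more chromosomes of given sizes
toy_map <- function(sizes) {
  chrom <- rep(sprintf("chr%d", seq_along(sizes)), sizes)
  pos <- unlist(lapply(sizes, seq_len))
  clone_map(sprintf("c%02d", seq_along(chrom)), chrom,
            (pos - 1L) * 100L + 1L, pos * 100L)
}

test_that("define_segments places breakpoints on any sample's status change", {
  cm <- toy_map(6)
  m <- cbind(S1 = c(0L, 0L, 1L, 1L, 1L, 0L),
             S2 = c(0L, 0L, 1L, 1L, 0L, 0L))
  segs <- define_segments(m, cm)
  expect_equal(nrow(segs), 4L)
  expect_equal(segs$first_clone, c(1L, 3L, 5L, 6L))
  expect_equal(segs$last_clone, c(2L, 4L, 5L, 6L))
  # base-pair extent spans first clone start to last clone end
  expect_equal(segs$start, c(1L, 201L, 401L, 501L))
  expect_equal(segs$end, c(200L, 400L, 500L, 600L))

  # all samples constant genome-wide: one segment per chromosome
  cm2 <- toy_map(c(4, 5))
  segs2 <- define_segments(matrix(1L, 9, 3), cm2)
  expect_equal(nrow(segs2), 2L)
  expect_equal(segs2$n_clones, c(4L, 5L))

  # single sample with k changes: k + 1 segments
  v <- c(0L, 1L, 1L, -1L, -1L, 0L)  # 3 changes
  expect_equal(nrow(define_segments(cbind(v), toy_map(6))), 4L)

  # missing calls do not break; change spanning a gap breaks before the
  # next observed clone
  vm <- cbind(c(0L, NA, NA, 1L, 1L))
  s <- define_segments(vm, toy_map(5))
  expect_equal(s$first_clone, c(1L, 4L))

  expect_error(define_segments(matrix(integer(0), 5, 0), toy_map(5)),
               "at least one sample")
})

test_that("define_segments agrees with a brute-force gap scan and tiles the genome", {
  set.seed(12)
  for (i in 1:60) {
    sizes <- sample(3:8, sample(1:2, 1), replace = TRUE)
    cm <- toy_map(sizes)
    m <- matrix(rand_status(nrow(cm) * 3, p_missing = 0.25), nrow(cm), 3)
    segs <- define_segments(m, cm)
    brk <- brute_breakpoints(collapse_amplification(m), cm$chrom)
    expect_equal(segs$first_clone, c(1L, which(brk) + 1L))
    # tiling: every clone in exactly one segment
    covered <- unlist(Map(seq, segs$first_clone, segs$last_clone))
    expect_equal(covered, seq_len(nrow(cm)))
    # invariant to sample order
    segs_perm <- define_segments(m[, c(3, 1, 2)], cm)
    expect_equal(segs_perm$first_clone, segs$first_clone)
  }
})

test_that("segment_status lifts clone status to segments", {
  cm <- toy_map(3)
  seg <- define_segments(cbind(c(1L, 1L, 1L)), cm)[1, ]
  expect_equal(segment_status(c(1L, 1L, 1L), seg), 1L)
  expect_equal(segment_status(c(NA, -1L, -1L), seg), -1L)
  expect_true(is.na(segment_status(c(NA, NA, NA), seg)))
  expect_error(segment_status(c(1L, 0L, 1L), seg), "disagree")
})

test_that("gnl_difference is the sign of the xenograft-minus-tumor status", {
  cm <- toy_map(2)
  m <- cbind(t = c(1L, 1L), x = c(0L, 0L))
  seg <- define_segments(m, cm)[1, ]
  # gain in tumor, normal in xenograft: decreased copy number -> -1
  expect_equal(gnl_difference(c(1L, 1L), c(0L, 0L), seg), -1L)
  expect_equal(gnl_difference(c(-1L, -1L), c(-1L, -1L), seg), 0L)
  # amplification collapses to gain: normal -> amp counts +1
  expect_equal(gnl_difference(c(0L, 0L),
                              collapse_amplification(c(2L, 2L)), seg), 1L)
  expect_equal(gnl_difference(c(-1L, -1L), c(1L, 1L), seg), 1L)
  expect_true(is.na(gnl_difference(c(NA, NA), c(0L, 0L), seg)))
})

test_that("recurrence thresholds: fraction of present pairs and presence floor", {
  # single-clone chromosome keeps every pair's profile constant per segment
  cm <- toy_map(1)
  n <- 12
  pairs <- data.frame(pair_id = sprintf("P%02d", 1:n),
                      tumor = sprintf("T%02d", 1:n),
                      xenograft = sprintf("X%02d", 1:n))
  tum <- matrix(0L, 1, n, dimnames = list(cm$clone_id, pairs$tumor))

  # 2 positive diffs out of 12 present: 2/12 < 0.30, not called
  xen <- matrix(0L, 1, n, dimnames = list(cm$clone_id, pairs$xenograft))
  xen[1, 1:2] <- 1L
  rr <- recurrent_differences(tum, xen, pairs, clone_map = cm,
                              config = recurrence_config())
  expect_true(rr$report$eligible[1])
  expect_equal(nrow(rr$gained), 0L)
  expect_equal(nrow(rr$lost), 0L)

  # 9 present comparisons, all positive: ineligible below 10 comparisons
  tum2 <- tum; tum2[1, 10:12] <- NA_integer_
  xen2 <- matrix(1L, 1, n, dimnames = list(cm$clone_id, pairs$xenograft))
  rr2 <- recurrent_differences(tum2, xen2, pairs, clone_map = cm,
                               config = recurrence_config())
  expect_equal(rr2$report$n_present[1], 9L)
  expect_false(rr2$report$eligible[1])
  expect_equal(nrow(rr2$gained), 0L)

  # 4 of 12 positive (>= 30% of present): called gained
  xen3 <- xen; xen3[1, 1:4] <- 1L
  rr3 <- recurrent_differences(tum, xen3, pairs, clone_map = cm,
                               config = recurrence_config())
  expect_equal(nrow(rr3$gained), 1L)
  expect_equal(rr3$gained$freq_pos, 4 / 12)

  expect_error(recurrence_config(min_pair_fraction = 0), "\\(0, 1\\]")
})

test_that("null cohorts yield no recurrent differences; planted segments are recovered", {
  null_sim <- gen_paired_cna(cna_sim_config(
    n_pairs = 20, n_chromosomes = 10, clones_per_chromosome = 60,
    n_events_per_tumor = 4, event_length = c(4, 12), shared_fraction = 1,
    private_event_rate = 0, missing_rate = 0.1, seed = 33))
  rr0 <- recurrent_differences(null_sim$tumor, null_sim$xenograft,
                               null_sim$pairs,
                               clone_map = null_sim$clone_map)
  expect_equal(nrow(rr0$gained), 0L)
  expect_equal(nrow(rr0$lost), 0L)

  planted <- list(chrom = 3L, from = 20L, to = 35L, sign = -1L,
                  carrier_fraction = 0.5)
  sim <- gen_paired_cna(cna_sim_config(
    n_pairs = 20, n_chromosomes = 10, clones_per_chromosome = 60,
    n_events_per_tumor = 4, event_length = c(4, 12),
    shared_fraction = 0.9, private_event_rate = 1, missing_rate = 0.1,
    recurrent_private_segments = list(planted), seed = 34))
  rr <- recurrent_differences(sim$tumor, sim$xenograft, sim$pairs,
                              clone_map = sim$clone_map)
  idx <- which(sim$clone_map$chrom == "chr3")[20:35]
  hit <- rr$lost$first_clone <= max(idx) & rr$lost$last_clone >= min(idx)
  expect_true(any(hit))
  # called frequency is consistent with the emitted truth carrier count
  n_carriers <- length(sim$truth$recurrent_segments[[1]]$carriers)
  called <- rr$lost[hit, ][1, ]
  expect_equal(called$n_neg, n_carriers)
})
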
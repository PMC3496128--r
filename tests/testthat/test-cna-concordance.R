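test_that("gnl_correlation restricts to altered clones and handles edges", {
  # identity with at least one altered clone
  a <- c(1L, 1L, 0L, -1L)
  expect_equal(gnl_correlation(a, a)$R, 1)
  # hand-worked example: eligible clones {1,2,4}, vectors perfectly opposed
  r <- gnl_correlation(c(1L, 1L, 0L, -1L), c(-1L, -1L, 0L, 1L))
  expect_equal(r$R, -1)
  expect_equal(r$n_altered_clones, 3L)
  # both all-normal: undefined, not zero
  r0 <- gnl_correlation(c(0L, 0L, 0L), c(0L, 0L, 0L))
  expect_false(r0$defined)
  expect_true(is.na(r0$R))
  # fewer than two eligible clones: undefined
  expect_false(gnl_correlation(c(1L, 0L), c(0L, 0L))$defined)
  # amplification collapsed before correlating
  expect_equal(gnl_correlation(c(2L, 0L, -1L), c(1L, 0L, -1L))$R, 1)
  # altered-in-both restriction drops clones altered on one side only
  rb <- gnl_correlation(c(1L, 1L, 0L, -1L), c(1L, 0L, 1L, -1L),
                        altered_in = "both")
  expect_equal(rb$n_altered_clones, 2L)
})

test_that("gnl_correlation matches brute-force Pearson and is symmetric", {
  set.seed(42)
  n_checked <- 0
  for (i in 1:120) {
    n <- sample(10:40, 1)
    a <- rand_status(n); b <- rand_status(n)
    r <- gnl_correlation(a, b)
    expect_equal(r$R, gnl_correlation(b, a)$R, tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(r$R, gnl_correlation(a[perm], b[perm])$R,
                 tolerance = 1e-12)
    if (r$defined) {
      ca <- collapse_amplification(a); cb <- collapse_amplification(b)
      sel <- which(!is.na(ca) & !is.na(cb) & (ca != 0L | cb != 0L))
      expect_equal(r$R, brute_pearson(ca[sel], cb[sel]))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 100)
})

test_that("correlation distance matrix matches brute force and flags undefined pairs", {
  set.seed(7)
  m <- matrix(rand_status(200, p_missing = 0.1), 50, 4,
              dimnames = list(NULL, paste0("S", 1:4)))
  d <- correlation_distance_matrix(m)
  expect_equal(diag(d), rep(0, 4), ignore_attr = TRUE)
  expect_equal(d, t(d))
  cm <- collapse_amplification(m)
  for (i in 1:3) for (j in (i + 1):4) {
    ok <- !is.na(cm[, i]) & !is.na(cm[, j])
    expect_equal(d[i, j], 1 - brute_pearson(cm[ok, i], cm[ok, j]))
  }
  # identical profiles -> 0; perfectly opposed -> 2
  p <- c(1L, -1L, 0L, 1L)
  dm <- correlation_distance_matrix(cbind(a = p, b = p, c = -p))
  expect_equal(dm["a", "b"], 0)
  expect_equal(dm["a", "c"], 2)
  # zero-variance profile: error names the pair
  flat <- cbind(a = c(0L, 0L, 0L), b = c(1L, 0L, -1L))
  expect_error(correlation_distance_matrix(flat), "\\(a, b\\)")
})

test_that("cluster_profiles reproduces group-average linkage", {
  # hand-computable 4-point UPGMA: A,B merge at 0.2; C,D at 0.3;
  # then group-average distance = mean of the 4 cross distances
  d <- matrix(c(0, .2, .8, .9,
                .2, 0, .7, .6,
                .8, .7, 0, .3,
                .9, .6, .3, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  hc <- cluster_profiles(d)
  expect_equal(hc$height, c(0.2, 0.3, mean(c(.8, .9, .7, .6))))
  ll <- sort(sapply(list(hc$merge[1, ], hc$merge[2, ]), function(k)
    paste(sort(hc$labels[-k]), collapse = "")))
  expect_equal(ll, c("AB", "CD"))

  # random matrices: merge structure agrees with stats::hclust average
  # linkage (compared through cophenetic distances, which are tie-robust)
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:9, 1)
    x <- matrix(rnorm(n * 6), n)
    rownames(x) <- paste0("S", seq_len(n))
    dd <- as.matrix(dist(x))
    hc1 <- cluster_profiles(dd)
    hc2 <- stats::hclust(as.dist(dd), method = "average")
    expect_equal(as.matrix(stats::cophenetic(hc1))[rownames(dd), rownames(dd)],
                 as.matrix(stats::cophenetic(hc2))[rownames(dd), rownames(dd)],
                 tolerance = 1e-12)
    expect_true(all(diff(hc1$height) >= -1e-12))  # ultrametric heights
  }

  # two well-separated pairs merge within-pair first
  d2 <- matrix(0.9, 4, 4, dimnames = list(paste0("S", 1:4), paste0("S", 1:4)))
  diag(d2) <- 0
  d2[1, 2] <- d2[2, 1] <- 0.1
  d2[3, 4] <- d2[4, 3] <- 0.1
  hc3 <- cluster_profiles(d2)
  expect_equal(sort(hc3$height[1:2]), c(0.1, 0.1))

  # single sample: degenerate single-leaf tree
  hc1leaf <- cluster_profiles(matrix(0, 1, 1, dimnames = list("S1", "S1")))
  expect_equal(nrow(hc1leaf$merge), 0L)
  expect_equal(hc1leaf$labels, "S1")
})

test_that("co-segregation counts sister-leaf pairs, verified by tree scan", {
  pairs2 <- data.frame(pair_id = c("P1", "P2"),
                       tumor = c("T1", "T2"), xenograft = c("X1", "X2"))
  ids <- c("T1", "X1", "T2", "X2")
  tight <- matrix(0.9, 4, 4, dimnames = list(ids, ids)); diag(tight) <- 0
  tight["T1", "X1"] <- tight["X1", "T1"] <- 0.1
  tight["T2", "X2"] <- tight["X2", "T2"] <- 0.1
  hc <- cluster_profiles(tight)
  expect_equal(as.integer(count_cosegregating_pairs(hc, pairs2)), 2L)

  # engineered: T1 closer to the foreign X2 than to its own X1
  eng <- matrix(0.9, 4, 4, dimnames = list(ids, ids)); diag(eng) <- 0
  eng["T1", "X2"] <- eng["X2", "T1"] <- 0.05
  eng["T2", "X2"] <- eng["X2", "T2"] <- 0.5
  hc2 <- cluster_profiles(eng)
  cnt <- count_cosegregating_pairs(hc2, pairs2)
  expect_equal(as.integer(cnt), brute_sister_count(hc2, pairs2))
  expect_false("P1" %in% attr(cnt, "cosegregating"))

  # all distances equal: deterministic tie rule, checked against oracle
  eq <- matrix(0.5, 4, 4, dimnames = list(ids, ids)); diag(eq) <- 0
  hc3 <- cluster_profiles(eq)
  expect_equal(as.integer(count_cosegregating_pairs(hc3, pairs2)),
               brute_sister_count(hc3, pairs2))

  expect_error(count_cosegregating_pairs(hc, data.frame(
    pair_id = "P9", tumor = "T1", xenograft = "nope")), "nope")
})

test_that("mean pair correlation rises with the shared-event fraction", {
  mean_R <- vapply(c(0.2, 0.5, 0.8, 1.0), function(sf) {
    sim <- gen_paired_cna(cna_sim_config(
      n_pairs = 12, n_chromosomes = 5, clones_per_chromosome = 60,
      n_events_per_tumor = 4, event_length = c(4, 12),
      shared_fraction = sf, private_event_rate = 0, missing_rate = 0,
      seed = 17))
    ct <- concordance_table(sim$tumor, sim$xenograft, sim$pairs)
    mean(ct$R[ct$defined])
  }, numeric(1))
  expect_true(all(diff(mean_R) > 0))
  expect_equal(mean_R[4], 1)
})
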
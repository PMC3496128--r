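test_that("probe filter keeps probes below floor in at most 85% of samples", {
  m <- rbind(all_low = rep(2, 10),
             all_high = rep(8, 10),
             borderline = c(rep(2, 17), rep(8, 3)))  # needs 20 samples
  m <- m[, c(1:10, 1:10)]  # recycle to 20 samples for rows 1-2
  m["borderline", ] <- c(rep(2, 17), rep(8, 3))
  f <- filter_probesets(m)
  expect_false("all_low" %in% f$kept)
  expect_true("all_high" %in% f$kept)
  # 17/20 = 85% exactly: boundary is inclusive, probe kept
  expect_true("borderline" %in% f$kept)
  # one more low sample crosses the threshold
  m["borderline", 18] <- 2
  expect_false("borderline" %in% filter_probesets(m)$kept)
  expect_error(filter_probesets(matrix(numeric(0), 0, 0)), "empty")
})

test_that("paired_outliers flags residual-percentile outliers", {
  set.seed(101)
  n <- 1000
  tum <- rnorm(n, 8, 2)
  names(tum) <- sprintf("p%04d", 1:n)

  # xenograft identical to tumor: degenerate residuals, nothing flagged
  r0 <- paired_outliers(tum, tum)
  expect_length(r0$over_probes, 0)
  expect_length(r0$under_probes, 0)

  # continuous noise: exactly 5% over + 5% under with distinct residuals
  xen <- tum + rnorm(n, 0, 0.5)
  r <- paired_outliers(tum, xen, pair_id = "P1")
  expect_length(r$over_probes, 50)
  expect_length(r$under_probes, 50)
  expect_length(intersect(r$over_probes, r$under_probes), 0)
  # flagged residuals are the extreme ones
  expect_true(all(r$residuals[r$over_probes] > r$thresholds["hi"]))
  expect_true(all(r$residuals[r$under_probes] < r$thresholds["lo"]))

  # residuals come from the least-squares fit of xenograft on tumor
  fit <- lm(xen ~ tum)
  expect_equal(unname(r$coefficients), unname(coef(fit)), tolerance = 1e-10)
  expect_equal(unname(r$residuals), unname(residuals(fit)), tolerance = 1e-10)

  # probe order invariance
  perm <- sample(n)
  r2 <- paired_outliers(tum[perm], xen[perm])
  expect_setequal(r2$over_probes, r$over_probes)
  expect_setequal(r2$under_probes, r$under_probes)

  # a strongly shifted probe lands in the under set
  xen3 <- tum + rnorm(n, 0, 0.5)
  xen3["p0007"] <- tum["p0007"] - 10 * 0.5
  expect_true("p0007" %in% paired_outliers(tum, xen3)$under_probes)

  expect_error(paired_outliers(rep(1, 100), rnorm(100)), "zero variance")
  expect_error(paired_outliers(rnorm(10), rnorm(10)), "at least 20")
})

test_that("recurrence_table counts pairs per probe with majority direction", {
  uni <- sprintf("g%02d", 1:40)
  res <- list(
    pair_de_result("P1", over_probes = c("g01", "g02"),
                   under_probes = "g03", universe = uni),
    pair_de_result("P2", over_probes = "g01", under_probes = "g03",
                   universe = uni),
    pair_de_result("P3", over_probes = "g01", under_probes = "g02",
                   universe = uni))
  rt <- recurrence_table(res, universe = uni)
  pp <- rt$per_probe[match(c("g01", "g02", "g03"), rt$per_probe$probe), ]
  expect_equal(pp$k, c(3L, 2L, 2L))
  expect_equal(pp$direction, c("over", "under", "under"))  # g02 tie -> under
  expect_equal(rt$table$n_probes[rt$table$k == 2], 2L)
  # tie rule is configurable
  rt2 <- recurrence_table(res, universe = uni, tie = "over")
  expect_equal(rt2$per_probe$direction[rt2$per_probe$probe == "g02"], "over")
  # sum rule: exact-k counts partition the union of flagged probes
  expect_equal(sum(rt$table$n_probes), 3L)
  expect_equal(sum(rt$table$n_over + rt$table$n_under),
               sum(rt$table$n_probes))
  # percentages computed on the declared universe
  expect_equal(rt$table$pct_universe[rt$table$k == 2], 100 * 2 / 40)
  expect_equal(rt$table$pct_universe[rt$table$k == 3], 100 * 1 / 40)

  res_bad <- c(res[1:2], list(pair_de_result("P4", "x01", character(0),
                                             universe = c(uni, "x01"))))
  expect_error(recurrence_table(res_bad), "inconsistent")
})

test_that("direction trend chi-square matches the textbook formula", {
  # counts with the structure of a strong direction reversal between
  # the exclusive-to-one-pair class and the common-to-many class
  uni <- sprintf("g%05d", 1:29683)
  counts <- rbind(a = c(over = 3114, under = 2416),
                  b = c(over = 6, under = 219))
  res1 <- pair_de_result("P1", over_probes = uni[1:3114],
                         under_probes = uni[3115:5530], universe = uni)
  many <- lapply(1:13, function(i)
    pair_de_result(paste0("Q", i), over_probes = uni[25001:25006],
                   under_probes = uni[25007:25225], universe = uni))
  rt <- recurrence_table(c(list(res1), many), universe = uni)
  ct <- direction_trend_chisq(rt, 1L, 10:14)
  expect_equal(unname(ct$counts), unname(counts))
  expect_equal(ct$statistic, brute_chisq_stat(counts), tolerance = 1e-12)
  expect_lt(ct$p_value, 1e-16)

  # equal proportions give statistic 0; swapping classes is symmetric
  eq <- list(pair_de_result("A", uni[1:10], uni[11:20], uni),
             pair_de_result("B", uni[31:40], uni[41:50], uni))
  rte <- recurrence_table(eq, universe = uni)
  cte <- direction_trend_chisq(rte, 1L, 1L)
  expect_equal(cte$statistic, 0)
  swapped <- direction_trend_chisq(rt, 10:14, 1L)
  expect_equal(swapped$statistic, ct$statistic)

  # zero margin is an error
  only_over <- list(pair_de_result("A", uni[1:10], character(0), uni))
  rto <- recurrence_table(only_over, universe = uni)
  expect_error(direction_trend_chisq(rto, 1L, 1L), "margin")
})

test_that("passage stability shares the paired_outliers contract", {
  set.seed(55)
  n <- 2000
  early <- rnorm(n, 8, 2); names(early) <- sprintf("p%04d", 1:n)
  expect_length(passage_stability(early, early)$over_probes, 0)

  # pure noise between passages: flagged sets show no recurrence above
  # chance across pairs (no probe flagged in all 4 pairs)
  res <- lapply(1:4, function(i)
    passage_stability(early, early + rnorm(n, 0, 0.3),
                      pair_id = paste0("pass", i)))
  rt <- recurrence_table(res)
  expect_equal(rt$table$n_probes[rt$table$k == 4], 0L)

  # planted drift in 20 probes recurs at the top level in every pair
  drift <- sprintf("p%04d", 101:120)
  res2 <- lapply(1:4, function(i) {
    late <- early + rnorm(n, 0, 0.3)
    late[drift] <- late[drift] - 3
    passage_stability(early, late, pair_id = paste0("pass", i))
  })
  rt2 <- recurrence_table(res2)
  high <- rt2$per_probe$probe[rt2$per_probe$k == 4]
  expect_true(all(drift %in% high))
})
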
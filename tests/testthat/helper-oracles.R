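# Independent brute-force oracles used to validate the implementation.
# These deliberately avoid the code paths (and where possible the base
# functions) used by the package itself.

# Pearson correlation from the definition
brute_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# average ranks computed from pairwise comparisons, then Pearson
brute_rank <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}
brute_spearman <- function(x, y) brute_pearson(brute_rank(x), brute_rank(y))

# Pearson chi-square from the textbook formula sum (O - E)^2 / E
brute_chisq_stat <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# hypergeometric upper tail P(X >= k) by direct summation of the pmf
brute_hyper_tail <- function(k, K, N, n) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i)
    choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
}

# segment boundaries by independent per-gap scanning: a gap (i, i+1)
# breaks iff the chromosome changes or some sample's status at the next
# clone (when observed) differs from its last observed status at <= i.
brute_breakpoints <- function(status, chrom) {
  n <- nrow(status)
  if (n < 2) return(logical(0))
  vapply(seq_len(n - 1L), function(i) {
    if (chrom[i] != chrom[i + 1L]) return(TRUE)
    for (s in seq_len(ncol(status))) {
      nxt <- status[i + 1L, s]
      if (is.na(nxt)) next
      prev_idx <- which(!is.na(status[seq_len(i), s]) &
                          chrom[seq_len(i)] == chrom[i + 1L])
      if (length(prev_idx) == 0L) next
      if (status[max(prev_idx), s] != nxt) return(TRUE)
    }
    FALSE
  }, logical(1))
}

# sister pairs read off an ape tree: two tips are sisters iff they attach
# to the same internal node
brute_sister_count <- function(hc, pairs) {
  phy <- ape::as.phylo(hc)
  parent_of_tip <- phy$edge[match(seq_along(phy$tip.label), phy$edge[, 2]), 1]
  names(parent_of_tip) <- phy$tip.label
  sum(vapply(seq_len(nrow(pairs)), function(i) {
    p1 <- parent_of_tip[[pairs$tumor[i]]]
    p2 <- parent_of_tip[[pairs$xenograft[i]]]
    p1 == p2 && sum(parent_of_tip == p1) == 2L
  }, logical(1)))
}

# random small status vectors/matrices for property tests
rand_status <- function(n, p_missing = 0.1) {
  v <- sample(c(-1L, 0L, 1L, 2L), n, replace = TRUE,
              prob = c(0.25, 0.4, 0.25, 0.1))
  v[runif(n) < p_missing] <- NA_integer_
  v
}
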
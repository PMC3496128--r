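---
title: "Methods: tumor-xenograft molecular concordance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tumor-xenograft molecular concordance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxconcord)
```

## The problem

Patient-derived xenografts (PDX) are established by grafting fresh tumor
fragments into immunodeficient mice and passaging them mouse-to-mouse.
Before such a panel can serve as a preclinical model, one must ask how
faithfully each xenograft preserves the molecular profile of the patient
tumor it came from: which copy-number alterations (CNAs) are shared,
which arise only in the graft, whether tumor and graft still fall in the
same molecular subtype, and which expression changes recur across grafts
— the classic signature being loss of human stromal transcripts, since
the mouse host replaces the human microenvironment.

`pdxconcord` implements that comparison as a reusable pipeline over two
paired data layers:

* **Copy number**: per-clone gain/normal/loss (GNL) status vectors on a
  fixed BAC/PAC-style clone grid, one tumor and one xenograft profile
  per pair (a patient may contribute two pairs, e.g. primary- and
  metastasis-derived grafts).
* **Expression**: probe-level log2 matrices (post-normalization scale)
  for the same pairs.

Because cohorts of this kind are rarely public, the package ships
simulators that generate both layers with known ground truth; every
stage is validated against those truths and against independent
brute-force oracles.

## Copy-number concordance

Statuses are integer codes: loss $-1$, normal $0$, gain $+1$,
amplification $+2$, with an explicit missing value (`NA`). Missing calls
model discarded low-quality spots and are never imputed or coerced to
normal. For correlation and segmentation, amplification is collapsed
into gain (`collapse_amplification()`), giving the 3-level GNL encoding;
the 4-level variant remains available via `collapse = FALSE` flags.

**Pair concordance.** `gnl_correlation()` computes the Pearson
correlation $R$ of the two status vectors restricted to clones that are
(i) non-missing in both profiles and (ii) altered in at least one of
them. Restricting to altered clones keeps the large normal fraction of
the genome from inflating $R$. Two deliberate choices:

* "Altered" defaults to *either* profile (`altered_in = "either"`);
  requiring both is available as a flag. With "both", clones where an
  alteration was gained or lost between tumor and graft would be
  excluded, which hides exactly the discordance of interest.
* With fewer than two eligible clones, or zero variance in either
  restricted vector (e.g. a profile whose only events are gains),
  the correlation is reported as *undefined*, never as 0. A pair of
  identical single-sign profiles is therefore undefined rather than 1;
  the `n_altered_clones` field lets the analyst see why.

**Cohort clustering.** `correlation_distance_matrix()` uses
$d(i,j) = 1 - r_{ij}$ over *all* mutually non-missing clones — the
clustering view is genome-wide, unlike the pair statistic.
`cluster_profiles()` performs group-average (UPGMA) agglomeration.
Merge ties are broken toward the pair of clusters whose lexicographically
smallest member labels sort first, which makes the tree fully
deterministic; the implementation is cross-checked against
`stats::hclust(method = "average")` through cophenetic distances.
A tumor-xenograft pair "co-segregates" when its two leaves are sisters
(their lowest common ancestor has exactly those two leaves below it);
weaker notions of clustering together are not well defined on arbitrary
tree shapes, so the strict sister-leaf rule is used and counted by
`count_cosegregating_pairs()`.

## Segments and recurrent GNL differences

`define_segments()` partitions the clone grid into maximal genomic
segments over which **every** sample in the cohort has constant status
(chromosome boundaries always break). Two numerical choices matter:

* Missing calls never induce breakpoints: for each sample a change is
  declared only between its two nearest non-missing values. When the
  change spans missing clones, the breakpoint is placed immediately
  before the later (next observed) clone. This is a convention — any
  position inside the gap would be consistent — and it is applied
  uniformly so segment sets are reproducible.
* Segmentation is performed on the collapsed 3-level codes by default:
  "constant copy number" is read as constant status, so an
  amplification inside a gained region does not split the region.

For each segment and pair, the *GNL difference* is
$\mathrm{sign}(s_{\text{xeno}} - s_{\text{tumor}})$ of the two segment
statuses: $+1$ means increased copy number in the xenograft, $-1$
decreased, `NA` when either side is missing over the whole segment.
`recurrent_differences()` then calls a segment recurrently gained
(lost) when:

* it is *present* — non-missing — in at least `min_comparisons`
  pairs (default 10), and
* positive (negative) differences occur in at least
  `min_pair_fraction` (default 0.30) of the **present** comparisons.

Using present comparisons as the denominator is an interpretation: with
all pairs as denominator, the presence filter would never change a
call, so the present-pair reading is the one under which both rules are
meaningful. A segment may be called in both directions.

## Paired differential expression

`filter_probesets()` removes probes indistinguishable from noise: a
probe is kept iff its signal is below the detection floor (default 3.5
log2 units) in at most 85% of samples, boundary inclusive.

`paired_outliers()` fits ordinary least squares of the xenograft
profile on the tumor profile — slope and intercept, under the null that
the two profiles are similar — and flags probes whose residual falls
outside the empirical 5th/95th percentiles of the residual
distribution. Choices:

* Orientation is xenograft on tumor, so a positive residual means
  higher expression in the xenograft. (Either orientation is
  defensible; this one makes "over"/"under" refer to the graft.)
* Percentiles are linearly interpolated order statistics
  (`quantile(type = 7)`) and the comparison is strict, which yields the
  exact-10% property: with $n$ distinct residuals, exactly
  $0.05n$ probes fall on each side.
* An all-equal (degenerate) residual distribution flags nothing.

`recurrence_table()` counts, for each flagged probe, the number of
pairs $k$ in which it is an outlier and assigns a direction at that
level by majority sign; ties go to under-expressed by default. The tie
rule is conservative with respect to the expected biology — highly
recurrent changes are dominated by stromal loss, i.e. under-expression
in the graft — and is configurable and reported.
`direction_trend_chisq()` compares the over/under split between two
recurrence classes (e.g. $k = 1$ versus $k \ge 10$) with a Pearson
chi-square on the 2x2 table, no continuity correction.
`passage_stability()` applies the identical residual contract to two
passages of the same xenograft.

## Molecular subtyping

`classify()` is a single-sample nearest-centroid rule: Spearman rank
correlation (average ranks for ties) of the sample against each subtype
centroid; the sample takes the best-correlated label unless the maximum
correlation is below 0.2, in which case it is Unclassified. A constant
sample vector leaves Spearman undefined and is reported Unclassified
with `NA` correlations. Ties between centroids resolve to the
lexicographically smallest label and are recorded in the call.
No per-gene centering is applied before correlating; users supplying
published centroids should confirm their expression values are on a
scale whose gene ranking is comparable to the centroid table's.
`match_genes()` handles gene-to-probe mapping, averaging multiple
probes per gene (median available), and `concordance_report()` flags
each patient concordant when all classified members share one label
(Unclassified members are excluded from the vote; with fewer than two
classified calls the vote is undefined and reported `NA`).

## Gene-set enrichment

`enrich()` is a plain one-sided hypergeometric over-representation
test: for a set with $K$ background members, a list of $n$ genes and
$k$ hits, $p = P(X \ge k)$ with population $N$, fold enrichment
$(k/n)/(K/N)$, and Benjamini-Hochberg correction across the collection.
The background defaults to the filtered probe/gene universe and is
always reported. The percent column is defined as $100k/n$ (list-based
denominator) and labelled as such; annotation-database-specific
variants (e.g. EASE-deflated counts) are deliberately not replicated.

## The simulators

`gen_paired_cna()` plants gain/loss events (uniform over valid start
positions, non-overlapping within a sample, resampling on collision
with an error after 100 attempts) in each tumor, retains each event in
the xenograft with probability `shared_fraction`, adds
Poisson-distributed sign-symmetric private events, applies configured
recurrent xenograft-private segments to a Bernoulli-drawn carrier
subset of pairs, and masks calls missing independently per clone and
sample. Defaults describe the study scale the package targets: 20
pairs, 20 chromosomes x 100 clones, 8 events per tumor of 5-40 clones,
85% event sharing, 2 private events per pair, 10% missingness.

`gen_paired_expression()` works directly on the post-normalization
log2 scale (normalization itself is explicitly not simulated): each
expressed probe has a baseline (truncated 1 log2 unit above the
detection floor), the tumor value adds noise, and the xenograft value
is the tumor value plus a fixed shift on a designated stromal subset
plus independent noise. Defaults: 13 pairs, 20,000 probes, 200 stromal
probes shifted by $-2$, noise sd 0.5. Low-signal probes are drawn
strictly below the floor in every sample. `gen_centroid_cohort()`
draws unit-spread centroids and samples as centroid plus noise.

What the simulators do **not** emulate: segmental correlation structure
along chromosomes beyond the planted events, subclonal (fractional)
copy-number states, probe-level GC or intensity biases, mouse-read
contamination, and correlated missingness. Passing recovery tests on
these cohorts therefore demonstrates that the statistical machinery is
correct under its own model, not that the thresholds are optimal for
any particular real platform. The private-alteration rate in real PDX
cohorts is not quantitatively established; the defaults were chosen
once for test power, not biological fidelity.

## Validation problem sizes

The shipped validation suite exercises: oracle equivalence of the six
core operations against brute-force reimplementations on 100+ random
small instances each; exact-10% outlier rates at $n = 1000$ over 20
seeds; recurrent-segment recovery on 20-pair x 2,000-clone cohorts with
planted carrier fractions 0.5-0.6 and 10% missingness over 20 seeds
(sensitivity is 1.0 at these conditions, with zero calls on matched
null cohorts); stromal-signature recovery on the default 13 x 20,000
expression cohort; sister-leaf co-segregation on 10-pair cohorts with
0.9 within-pair versus 0.5 background agreement; and perfect noiseless
subtype recovery with Unclassified calls for decorrelated samples.
`scripts/acceptance.R` recomputes all of these from scratch at a
caller-supplied seed.

## Known limitations

* The threshold status caller (`assign_status()`) is declared plumbing:
  real aCGH ratio data should be segmented with a dedicated caller
  (GLAD, CBS, ...), whose effective thresholds a fixed cutoff cannot
  reproduce. The ±0.25/+1.0 defaults are configuration, not doctrine.
* UPGMA on correlation distance is one conventional reading of
  "group-average clustering of status profiles"; other linkages will
  produce different co-segregation counts on borderline cohorts.
* The sister-leaf co-segregation rule is strict: a pair separated by a
  single intervening leaf counts as not co-segregating.
* Quantities defined on unreleased cohorts (published correlation
  tables, region counts, subtype call tables) are inputs to this
  package, not outputs it can reproduce.
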
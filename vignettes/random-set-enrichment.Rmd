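---
title: "Stage-wise Random-Set enrichment: model, calibration and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-wise Random-Set enrichment: model, calibration and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsstages)
```

## The model

`rsstages` tests whether a predefined gene set is enriched for genes
differentially expressed between two phenotype classes (normal mucosa
versus one tumor stage), and tracks those calls across successive tumor
stages. The gene-level score is the rank of the classical two-sample
t-statistic, oriented tumor minus normal: the most tumor-downregulated
gene on a G-gene array has rank 1, the most upregulated rank G. The
set-level statistic is the Random-Set score — the mean member rank
standardized by the exact mean and variance of a mean of n scores drawn
*without replacement* from the array:

$$ z = \frac{\bar x - \mu_0}{\sigma_0}, \qquad
   \mu_0 = \bar r, \qquad
   \sigma_0^2 = \frac{\widehat{\sigma}^2_r}{n}\cdot\frac{G-n}{G-1}, $$

with $\bar r$ and $\widehat{\sigma}^2_r$ the population mean and
variance of the realized rank vector. These are the simple-random-
sampling moments of a sample mean, exact for any score vector; for
untied ranks they reduce to $\mu_0 = (G+1)/2$ and
$\sigma_0^2 = (G+1)(G-n)/(12n)$. Computing them from the realized
vector rather than the closed form keeps them exact under average-tie
ranks — the two agree to machine precision when no ties exist (the test
suite checks both against exhaustive subset enumeration for every
G ≤ 12).

Two nulls are in play, deliberately. The standardization by
$(\mu_0, \sigma_0)$ compares the set against random same-size gene sets
(a competitive null, approximately Gaussian for moderate n, reported as
the `p_analytic` diagnostic). The *headline* nominal p-value instead
comes from permuting the phenotype labels and recomputing the entire
pipeline — t-statistics, ranks, z — in each permutation. Label
permutation preserves inter-gene correlation, which the Gaussian
approximation ignores; the simulator's `rho` option exists precisely to
demonstrate that gap (equicorrelated sets inflate the analytic p's
type-I error but leave the permutation p calibrated).

## The permutation p-value

For a set with observed score $z_{obs} > 0$ the p-value is
$\#\{b : z_b \ge z_{obs}\} / \#\{b : z_b \ge 0\}$, mirrored for
negative scores. Two design points deserve explanation:

* **One-sided in the observed direction.** Up- and down-regulated
  pathways are reported in disjoint tables, each gated at the same
  cutoff, so the test of record is directional.
* **Same-sign denominator.** Dividing the tail count by all B
  permutations would make the *reported* p (whose direction is chosen
  by the data) stochastically smaller than uniform — a null set would
  be flagged at rate 2α. Normalizing by the count of same-signed
  permutations is the standard remedy for signed enrichment statistics
  (weighted-KS implementations do the same), and restores a uniform
  null p: the type-I acceptance test holds the empirical rate at
  α within binomial error, and a Kolmogorov–Smirnov check cannot
  distinguish the null p histogram from Uniform(0,1).

The default estimator is the plug-in tail fraction, which can be
exactly 0 when no permuted score reaches the observed one — matching
how strongly enriched pathways are conventionally reported. The
smoothed estimator (b+1)/(B_same+1) is available and preferable
whenever p-values feed downstream inference. With the default B = 1000,
the granularity of the p-value is ~1/500 per tail; B below 100 triggers
a warning because calls at α = 0.05 become coarse. A
Benjamini–Hochberg column is emitted for reference but never gates the
calls, which use the nominal p at α = 0.05 as is conventional for
exploratory pathway screens.

Permutations are shared across sets within a contrast (one label
shuffle scores every set), making results invariant to set order and
reproducible from a single seed. Permutations are drawn uniformly
without enforcing uniqueness, the standard Monte-Carlo practice; with
60 samples the chance of a repeated permutation is negligible.

## Gene-level choices

The paper-trail behind two parameters that are genuinely
underdetermined:

* **Pooled versus Welch t.** The pooled-variance (Student) form is the
  default — it is the textbook two-sample t and the default of the
  common numerical environments — with Welch available via
  `var_equal = FALSE`. Since only ranks enter the statistic, the choice
  matters little unless class variances differ wildly.
* **Degenerate genes.** A gene with zero pooled variance and unequal
  class means has an unbounded t. Because ranks, not magnitudes, enter
  the statistic, such genes are placed at the extreme rank in the
  direction of their mean difference (with a warning) instead of
  propagating infinities. Zero variance with equal means scores t = 0.

## Stage orchestration and reporting

Each tumor stage is contrasted independently against the shared normal
samples. Per-stage calls merge into a trajectory table (direction and p
per stage; p is reported only where the call is non-none, so printed
rows read like the conventional tables with `-` in non-significant
cells), and each pathway lands in one of the 7 non-empty cells of the
three-stage Venn diagram per direction. `venn_marginals()` inverts the
partition back to per-stage counts — a conservation identity the tests
assert both on simulated output and on the bundled published tables
(23/41, 21/29, 33/25 up/down at SPL/LPL/CRC; 112 pathways in total).

The clustering diagnostic uses Euclidean distance with Ward's
minimum-increase-of-within-cluster-variance linkage — the criterion
some environments label "inner squared distance" — via `hclust`'s
`ward.D2`, which applies Ward's rule to unsquared Euclidean input.
Agglomeration is deterministic, so the two-cluster misclassification
count (minimized over the two cluster-to-label assignments) is
reproducible. PCA is gene-centered, making the projection invariant to
per-gene location shifts.

## The synthetic-data generator

`sim_config()` defaults describe the study conditions the pipeline
targets: G = 2000 genes, 30 + 30 samples, 50 sets with sizes uniform on
8–400 (the span of curated canonical-pathway collections), unit
Gaussian noise on the log2 scale, and per-gene baselines uniform on
(4, 12) to mimic array intensities — the baseline range is cosmetic,
since every statistic in the package is location-invariant per gene.
Planted sets shift a fraction `f` of members by `delta` noise-SDs in
the tumor class; ground truth is returned alongside the data. Genes are
independent by default; `rho` adds an equicorrelated within-set factor.

What the simulator does *not* emulate: probe-level effects and
summarization, batch effects, heavy-tailed or heteroscedastic noise,
correlated baselines between overlapping sets, and the histology
covariates of real cohorts. Passing tests therefore demonstrate
statistical correctness and calibration of the machinery, not
robustness to every artifact of real array data.

One behavior of competitive rank-based tests is visible even in clean
simulations: planting a large set shifts the ranks of *all* other
genes, so unplanted sets drift slightly in the opposite direction. This
is a property of the statistic, not a bug, and is shared by every
competitive enrichment method.

## Validation arms

* **Weighted-KS score.** An independent enrichment statistic (running
  sum, hits weighted by |metric|^q, misses by 1/(G−n), signed maximum
  deviation) under the identical permutation design. At q = 0 it is
  exactly the two-sample KS statistic between hit and miss positions —
  asserted against a brute-force walk and an external implementation.
  The default gene metric is signal-to-noise with the usual 0.2 floors;
  pooled t is available for symmetry with the RS arm. On fully planted
  sets the two arms agree in direction in ≥ 95% of replicates.
* **List overlap.** `overlap_fisher()` computes the one-sided
  hypergeometric tail over a configurable pathway universe (880, the
  number of sets tested, for within-study comparisons; configurable
  because cross-platform universes are study-specific).
* **Set-size contrast.** `setsize_comparison()` runs the one-tailed
  pooled t-test of whether down-regulated pathways are larger than
  up-regulated ones, reproducing the published means (27.9 vs 69.0
  RefSeqs) and p = 2.4e-4 from the bundled tables.

## Numerical and testing notes

Problem sizes in the test suite are chosen to finish in well under a
minute per file on one CPU: null calibration uses 2000 sets at B = 200
(binomial 3-SE band around α), power monotonicity uses 50 replicates
per configuration at B = 99 on a 500-gene array, with monotonicity
asserted up to twice the binomial standard error of each difference —
the principled allowance for Monte-Carlo noise at 50 replicates, not a
tuning knob. Exact oracles (subset enumeration, brute-force walks,
log-factorial hypergeometric summation) are kept independent of the
implementation paths they check.

## Known limitations

* Membership is resolved by exact string match between GMT members and
  array identifiers; no symbol/RefSeq mapping layer is provided.
* Missing expression values are rejected rather than imputed (upstream
  RMA-style summaries contain none).
* No FDR-gated calling: the nominal p at 0.05 is the decision rule, as
  in the published tables the package reproduces; the BH column is
  informational.
* The GSEA arm implements the enrichment score and phenotype
  permutation only — no gene-tag permutation mode, FDR q-values, or
  leading-edge analysis.
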
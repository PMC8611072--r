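---
title: "chronet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chronet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronet)
```

## The problem

Dense differentiation time courses — chromatin accessibility (DNase I
hypersensitive site densities) and gene expression sampled daily across
donors — make it possible to ask not just *which* regulatory elements and
genes change, but *when*, *together with what*, and *under whose control*.
`chronet` implements that inference chain as a reusable pipeline:

1. call developmentally regulated DHSs and genes (spline regression +
   likelihood-ratio test + abundance/fold filters),
2. cluster the regulated features into sequential temporal classes,
3. link distal DHSs to target genes by temporal correlation within a
   genomic window,
4. test transcription-factor motif enrichment per temporal class,
5. model each DHS's accessibility from the expression of its
   motif-compatible TFs with elastic-net regression, with hyperparameters
   selected per temporal cluster,
6. benchmark those coefficients against raw motif counts with a naive
   Bayes cluster classifier,
7. resolve TFs and their positively associated DHSs into sequential
   regulatory modules (cosine-distance hierarchical clustering), and
8. assemble stage-specific TF-to-gene networks with standardized edge
   weights and node centralities.

A synthetic-data module generates full datasets with planted structure so
that every stage can be verified quantitatively without any external data.

## Developmental regulation calls

Per-sample values are quantile-normalized: each column is forced onto the
cross-sample mean reference distribution, and a group of tied values
receives the mean of every reference slot it occupies (so a constant
column maps to the mean of the reference). This slot-mean tie rule is
implemented directly; it differs from interpolation-based variants for
ties spanning more than two slots.

Each feature's mean-centered profile is regressed on a cubic spline of
day with 3 degrees of freedom. We use a natural cubic spline
(`splines::ns`) with boundary knots at the day range; its two internal
knots then fall at the day tertiles. This is the unique basis that
delivers both "cubic spline" and "3 df" with a fixed, reproducible knot
rule. Significance comes from a likelihood-ratio test against an
intercept-only null:

* **ols mode** (default in tests, exactly reproducible): LRT =
  `n * log(RSS_null / RSS_full)`, referred to a chi-square with 3 df.
  With 13 days x 3 donors this reference is mildly anticonservative (the
  exact small-sample reference is an F distribution), which is why the
  null calibration check brackets the fraction of p < 0.01 in
  [0.005, 0.02] rather than pinning it at 0.01.
* **robust mode**: both models are fit by iteratively reweighted least
  squares with the bisquare psi (tuning constant 4.685, `MASS::rlm`) and
  the statistic is twice the difference of robustified deviances
  (`sum(rho(residual / s))`), evaluated at the full model's scale
  estimate and referred to the same chi-square(3). The literature offers
  several robust LRT flavors; this one is simple, monotone in the fit
  improvement, and reduces to the Gaussian LRT as the weights approach
  one. ols mode is the reference that the oracle tests pin down exactly.

A feature is called regulated when all three hold: BH-adjusted p < 1e-5,
log2 fold-range of the per-day means >= 1 (computed on raw daily means
with a pseudocount of 0.5 against zero minima), and a maximum daily mean
of at least 30 normalized counts (DHSs) or 2 FPKM (genes). Direction
compares the mean fitted value over the last two days against the first
two; differences below 5% of the fitted range are "other". The
fitted-value rule is a package choice; the fold filter uses raw daily
means because fitted values can undershoot sharp transients.

## Temporal clustering and the enrichment matrix

Regulated features are z-scored per day and clustered with Euclidean
k-means (k = 5 by default, best of 50 restarts). Cluster labels are
renumbered so that cluster-mean peak days are non-decreasing; ties (e.g.
two classes peaking on day 0) are broken by the profile's center of mass,
making "E1" the earliest program. The label ordering is cosmetic —
recovery is scored with the adjusted Rand index, which ignores labels.

The gene-cluster x DHS-cluster matrix counts regulated DHSs whose
midpoint falls within +/-50 kb of any TSS of the gene cluster
(TSS-centered windows; the alternative DHS-centered reading is
equivalent up to the same pair set). Expected counts assume cluster
membership is independent of window occupancy; the enrichment score is
`log2((obs + 0.5) / (exp + 0.5))` and each cell carries a chi-square test
(no continuity correction) on the corresponding 2x2 table, with
expected-below-5 cells flagged.

## DHS-gene linking

Candidate pairs are same-chromosome (DHS midpoint, TSS) pairs within
+/-1 Mb. The link statistic is the Pearson correlation of per-day mean
profiles — per-day means rather than per-sample values, because the
question is about temporal shape, not donor noise. Two printed variants
are preserved behind a flag: discovery links use `|r| > 0.7` (strict
inequality), network links use `r >= 0.7` positive-only. Distances are
signed and strand-aware for reporting. Zero-variance profiles are
skipped and counted.

## Motif enrichment

Presence/absence of a motif in a DHS (>= 1 hit) is tested per temporal
cluster with one-tailed hypergeometric tails — `P[X >= k]` for
over-representation, `P[X <= k]` for under-representation — and BH
adjustment across all (motif, cluster) pairs. The default universe is
the clustered (changing) set; the full detected set is available by
flag. Individual motifs are tested; an optional motif-to-archetype map
collapses degenerate families first. Motif scanning itself is upstream
input: either a pre-intersected table or FIMO output assigned to DHSs by
the motif-midpoint-in-interval rule (a midpoint exactly at a BED `end`
does not overlap).

## Elastic-net TF models

For each regulated DHS, candidate TFs must (i) have a motif hit in the
DHS, (ii) exceed 2 FPKM maximum daily expression and (iii) by default be
developmentally regulated themselves. Predictors are TF per-day profiles
z-scored across days; the response is the DHS per-day mean density,
centered. The fit minimizes

$$\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 +
\lambda\left(\alpha\lVert\beta\rVert_1 +
\tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\right)$$

by cyclic coordinate descent over a warm-started decreasing lambda path
(Gram-matrix updates; unpenalized intercept). Convergence is declared
when the largest coefficient update falls below the tolerance *relative
to the response SD* (default 1e-7), so count-scale and unit-scale
problems converge to the same relative precision. Correctness is pinned
by KKT checks, the closed-form ridge solution at alpha = 0, the lasso
null threshold, and agreement with an independent solver on
unit-variance responses.

Hyperparameters are selected **per temporal cluster**, not per DHS: for
each of `nRepeats` random held-out sets of 4 days, every modelable DHS in
the cluster is fit on the remaining days across the (alpha, lambda) grid
and scored by held-out MSE. The cluster objective is the sum over DHSs
of (mean MSE + SE across repeats); the minimizing pair wins, with ties
broken toward larger lambda and then larger alpha — the sparsest model,
which also makes the all-zero region of a pure-noise cluster resolve to
the largest grid penalty. Repeated random leave-4-days-out validation is
the only reading of a "100-fold" protocol that is executable with 13
time points; the repeat count is configurable. Validation fits use a
looser tolerance (1e-4 relative, 200-sweep cap) because held-out MSE is
insensitive at that scale; final refits always use the full tolerance.
The full grids (101 alphas, 100 lambdas, 100 repeats) remain available;
the pipeline default is a reduced 11 x 20 grid with 20 repeats, which
selects indistinguishable penalties on the synthetic conditions at a
fraction of the cost.

## The naive Bayes benchmark

To ask whether fitted temporal associations carry more class information
than raw motif content, the DHS's temporal cluster is predicted from
either (a) discrete motif counts under per-class Poisson likelihoods
(rate = class mean + 0.1 pseudorate) or (b) elastic-net coefficients
under per-class Gaussians (variance floored at 1e-6), with class priors
from the training fold and stratified 5-fold cross-validation
(resubstitution behind a flag). The reported ratio (coefficient accuracy
over count accuracy) exceeding 1 reproduces the qualitative finding that
regression coefficients beat motif counts.

## Regulatory modules and networks

TFs positively associated with at least `minPositiveDhs` DHSs (default
200, the headline-scale threshold; scale it with the DHS universe — the
synthetic acceptance runs use 10) are clustered by average-linkage
agglomeration on cosine distances between their full coefficient vectors
(zeros included — restricting to positive DHSs would discard the shared
sparsity structure that separates programs). The tree is cut at k = 5
and modules are numbered by the mean peak day of their member TFs'
positively associated DHS profiles. Module DHS sets are unions over
member TFs and may overlap between modules.

Stage networks take a stage-specific TF list (in the pipeline, each
module's members; in general, any user-supplied list), connect each TF
to its positively associated DHSs, and each DHS to its positively
correlated (r >= 0.7) target genes. Multi-DHS paths aggregate by
summing per-DHS products of coefficient and correlation (a max-product
variant is available). Standardized weights have mean 0 and sample-SD 1
per network (two edges standardize to +/- 1/sqrt(2)); a single-edge
network gets 0 by convention. Degree centrality (normalized by n - 1) is
the default; betweenness and per-component eigenvector centrality are
selectable. Per-TF target lists can be truncated to the top 50 by
|standardized weight|, ties resolved toward the lexicographically
smaller gene id.

## The synthetic-data generator

The generator emulates a 13-day (days 0..12), 3-donor course with five
sequential regulatory programs: two silencing logistic ramps, one
transient bump (difference of two logistics), and two activation ramps.
The temporal position of a program is a *module* property; member TFs
jitter around it (midpoint shift up to +/-0.4 days, steepness factor
0.85-1.2), keeping modules separable while making members
distinguishable. TF expression is the program curve times a gain
(5-60 FPKM) plus Gaussian noise; two flat decoy TFs (one under the 2 FPKM
floor) exercise the candidacy filters.

A changing DHS combines 1-2 positive effects from its own module's TFs —
and, with probability 0.2 for ramp classes, a weak negative effect from
the opposite ramp class, whose negated curve runs in the DHS's own
direction (so class shapes stay monotone/unimodal while planting
negative coefficients for sign-accuracy scoring). The latent combination
passes through a softplus and is rescaled to a 40-150 count range
(non-changing DHSs are flat at 5-80 counts); replicate noise is Gaussian
with SD equal to `noise_sd` (default 0.1) times the dynamic range.
Gaussian noise on the normalized-signal scale is deliberate: downstream
stages operate on quantile-normalized densities, and raw-count
(negative binomial) realism is out of scope.

Changing genes are weighted sums of 1-3 exclusive same-module enhancer
DHSs, rescaled to an FPKM range with a maximum above 2. Every planted
enhancer lies within the 1 Mb window of its gene's TSS (proximally
biased offsets); additional changing DHSs of the same module are placed
at 1.2-2x the window to probe window exclusion, non-changing DHSs sit
inside windows as correlation-free decoys, and everything else lives in
a distal zone clear of all gene windows. Motif hits consist of one hit
(count 1-3) per true effect plus background hits: each (DHS, TF) pair
draws a Poisson count with mean `decoy_motif_rate` (default 0.5, i.e.
roughly 39% of TF motifs present per DHS without any causal role). That
level of degeneracy is what makes the motif-count naive Bayes weak and
the coefficient-based classifier strong — the phenomenon the benchmark
exists to measure.

What the generator does **not** emulate: raw read counts and their
overdispersion, donor-specific effects, overlapping or nested DHSs,
multi-TSS genes, co-regulation confounding between neighbouring genes
(planted enhancers are exclusive to one gene), and motif
position/affinity effects. Passing tests therefore demonstrate the
correctness and calibration of the machinery under the planted model,
not performance guarantees on real chromatin data.

## Numerical choices and degenerate inputs

* Zero-variance profiles: LRT statistic 0 with p = 1; excluded from
  z-scoring and correlation with counters rather than NaNs.
* Pseudocounts: 0.5 on fold-range denominators and on
  observed/expected in the enrichment score; 0.1 pseudorate in the
  Poisson naive Bayes; 1e-6 variance floor in the Gaussian one.
* Tie-breaks are always deterministic and documented: k-means labels by
  peak day then center of mass; CV grid ties toward larger lambda then
  alpha; naive Bayes prediction ties toward the lowest class index;
  top-target ties toward the smaller gene id.
* All randomness flows from explicit integer seeds; stage-level seeds
  are derived from the global seed with a fixed hash, and two runs with
  the same configuration produce byte-identical output tables (numbers
  are printed with 12 significant digits, plain notation down to 1e-4).
* Problem sizes used by the test-suite study conditions: 400 DHSs / 100
  genes / 40 TFs for the end-to-end runs (2,000 DHSs for the
  regulated-call recovery and null-calibration checks; 200 DHSs across
  20 seeds for the classifier-direction check) — chosen so the planted
  per-cluster and per-module counts stay large enough for stable
  recovery statistics.

## Known limitations

* The robust-mode LRT reference is approximate; use ols mode when exact
  calibration matters.
* Per-cluster hyperparameter selection assumes cluster members share a
  noise scale; a cluster mixing very bright and very dim DHSs lets the
  bright ones dominate the summed objective.
* The enrichment matrix's expected-count model conditions only on
  marginal shares, not on genomic covariates (GC, gene density).
* Networks standardize edge weights per network, so weights are not
  comparable across stages.
* `runPipeline` recomputes every stage on each call rather than caching
  stage outputs by input checksums; runs are short enough on the
  supported problem sizes that a cache would add failure modes (stale
  invalidation) for little gain. The manifest's per-file MD5 checksums
  let an external workflow manager skip unchanged stages if needed.
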
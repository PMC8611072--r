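# chronet

Temporal regulatory-module inference from dense differentiation time
courses of chromatin accessibility and gene expression.

## The problem

A differentiating cell population sampled daily — DNase I hypersensitive
site (DHS) densities and gene expression from several donors — contains
far more than a list of differential features: the *timing* of chromatin
opening and closing, the pairing of distal elements with the genes they
drive, and the transcription factors (TFs) whose expression changes
explain each element's trajectory. `chronet` turns those questions into
one reproducible pipeline for anyone with a feature-by-sample matrix, a
sample sheet (donor, day), DHS intervals, TSS annotation and a motif-hit
table:

1. **Developmental regulation.** Quantile-normalize, then for each
   feature fit a cubic spline of day (3 df) and test it against an
   intercept-only null with a likelihood-ratio test,
   `LRT = n log(RSS0/RSS1)` vs chi-square(3) (a robust IRLS variant is
   available). A feature is regulated when BH-adjusted p < 1e-5, log2
   fold-range >= 1, and maximum daily mean >= 30 counts (DHS) or 2 FPKM
   (gene).
2. **Temporal classes.** k-means (k = 5) on z-scored per-day profiles,
   labels ordered by peak time (E1..E5 / G1..G5), plus a gene-cluster x
   DHS-cluster enrichment matrix (log2 observed/expected within +/-50 kb
   of TSSs, chi-square per cell).
3. **DHS-gene links.** Pearson correlation of per-day profiles for all
   same-chromosome pairs within +/-1 Mb of the TSS; `|r| > 0.7` keeps a
   link (positive-only `r >= 0.7` variant for networks).
4. **Motif enrichment.** One-tailed hypergeometric over/under-
   representation of motif presence per temporal class, BH-adjusted.
5. **TF models.** Each regulated DHS's per-day density is an elastic-net
   function of the z-scored expression of its motif-compatible,
   expressed (and by default regulated) TFs:
   `min (1/2n)||y - b0 - Xb||^2 + lambda(alpha||b||_1 + (1-alpha)/2 ||b||_2^2)`,
   with `(alpha, lambda)` selected per temporal cluster by repeated
   leave-4-days-out validation (objective: sum over DHSs of held-out
   MSE + SE; ties toward the sparser model).
6. **Benchmark.** A naive Bayes classifier predicts each DHS's class
   from Poisson-modeled motif counts vs Gaussian-modeled coefficients;
   the accuracy ratio quantifies what the temporal modeling adds.
7. **Modules.** TFs positively associated with enough DHSs are clustered
   by cosine distance of their coefficient vectors (average linkage,
   k = 5) into sequential regulatory modules.
8. **Networks.** Stage-specific TF -> gene graphs via positive
   coefficients and positive links; edge weight = standardized sum of
   coefficient x correlation; degree/betweenness/eigenvector
   centralities; top-50 targets per TF.

A first-class synthetic-data generator plants all of this structure
(module activity curves, TF -> DHS effects, enhancer -> gene links, decoy
motifs, decoy placements) and ships a truth ledger, so every stage is
verified end-to-end by recovery scoring without downloading anything.

## Worked example

```r
library(chronet)

sim <- generateDataset(simulationConfig(seed = 42))
sim$dhs
#> TimeCourseExperiment: 400 features x 39 samples
#>   days: 0..12 (13 distinct), donors: 3

dn   <- quantileNormalize(sim$dhs)
fits <- callRegulated(fitDevelopmentalModel(dn, mode = "ols"),
                      featureKind = "dhs")
table(regulated = fits$regulated, direction = fits$direction)
#>          direction
#> regulated activated other silenced
#>     FALSE       188    23       69
#>     TRUE         53    18       49
```

120 of 400 DHSs are called developmentally regulated (the generator
planted 120), split into activated and silenced programs. The whole
chain runs from one config:

```r
res <- runPipeline(chronetConfig(simulation = simulationConfig(seed = 42),
                                 minPositiveDhs = 10, seed = 42))
res$tfModel
#> TFCoefficientMatrix: 120 DHSs x 38 TFs
#>   nonzero coefficients: 1347 | unmodelable DHSs: 0
#>   clusters: E1(a=0.90,l=0.546) E2(a=0.40,l=0.0483) E3(a=0.90,l=0.546)
#>             E4(a=0.70,l=0.162) E5(a=0.90,l=0.162)
head(res$links, 3)
#>     dhs_id  gene_id         r distance
#> 1 dhs00001 gene0001 0.9915982    -2038
#> 2 dhs00006 gene0001 0.9845870   295981
#> 3 dhs00002 gene0002 0.9853715   403775
str(res$recovery)
#> $ dhs_changing        : 1 1 1          (precision, recall, F1)
#> $ links               : 1 1 1
#> $ cluster_ari         : 1
#> $ module_ari          : 0.937
#> $ effect_recovery     : 0.956
#> $ effect_sign_accuracy: 0.995
res$networks[[1]]
#> TFNetwork: 8 TFs, 25 genes, 78 edges
```

Every planted enhancer-gene link is recovered at `|r| > 0.7` with no
false positives; the temporal clusters match the planted classes
exactly (adjusted Rand index 1), 95.6% of planted TF -> DHS effects come
back with a nonzero coefficient and 99.5% of those carry the planted
sign; cosine clustering of the coefficient vectors reassembles the five
planted modules (ARI 0.94). With `outDir =` the run also writes every
stage table (TSV), the networks (GraphML + edge lists) and a JSON
manifest with parameters and checksums; reruns with the same seed are
byte-identical. `runPipeline` equally accepts on-disk inputs (matrix +
sample-sheet TSVs, BED intervals and TSSs, FIMO or pre-intersected
motif hits) via `chronetConfig(inputs = ...)`, and
`inst/scripts/chronet-run.R` wraps it for the shell with a YAML config.

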
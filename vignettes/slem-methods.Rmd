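---
title: "Stepwise learning of sparse biologically labelled networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise learning of sparse biologically labelled networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Genome-wide association studies report many common risk variants for
polygenic diseases such as schizophrenia, but single SNPs have small effects
and say nothing about how variants act together through molecular and
cellular intermediates. This package implements a two-step strategy for
learning an *interpretable* genotype-to-diagnosis model from two kinds of
data of very different precision and size:

1. **Architecture from precise multilevel data.** A small cohort assayed at
   several biological levels (genotypes; transcript-isoform expression;
   protein markers; cellular phenotypes) determines a five-layer network
   SNPs → isoforms → markers → phenotypes → disease. Features significantly
   associated with the risk SNPs become nodes; pairwise association
   statistics between adjacent layers become signed initial weights; weak
   edges are masked out.
2. **Weights from large end-to-end data.** The sparse, labelled network is
   then trained as an ordinary feed-forward classifier (tanh hidden units,
   sigmoid output, no biases) on a large cohort that has only genotypes and
   a binary diagnosis, with every gradient multiplied by the binary edge
   mask so discarded edges stay exactly zero.

Because every node carries a biological label, the trained network supports
mechanistic readouts: per-SNP *impact scores* (the absolute sum over all
unmasked paths of the product of edge weights), *mediator modules* (the
strong-edge subnetwork feeding chosen phenotype nodes), and an exhaustive
screen of genotype-state *combinations* of the top-impact SNPs, scored by
precision (patients among carriers) and hypergeometric enrichment and then
re-evaluated on an independent cohort.

### Statistical components

* **SNP-sourced associations** are covariate-adjusted ordinary least squares:
  the response is regressed on `[1, genotype, covariates]` and the genotype
  slope's two-sided t-test p-value is used. The batch engine residualises
  both sides against the covariate design once (Frisch–Waugh–Lovell) and
  then reduces each pair to a simple regression; this is algebraically
  identical to the per-pair fit and is verified against an explicit
  normal-equation oracle to 1e-8.
* **Upper-layer associations** (isoform–marker, marker–phenotype) use the
  Kendall rank correlation (tau-b with tie correction), because
  neuropathology-style readouts need not be normally distributed. The
  p-value is exact for n ≤ 10 without ties and a continuity-corrected
  normal approximation otherwise; the two branches agree within 0.02 at
  n = 10.
* **Node selection** keeps targets whose minimum Benjamini–Hochberg
  q-value over all risk SNPs falls below per-layer thresholds, 0.1 for the
  isoform layer and 0.05 for the marker and phenotype layers. The looser
  isoform threshold reflects the very large number of SNP × isoform tests
  relative to the cohort size.
* **Edge initialization** converts each adjacent-layer p-value into a signed
  weight on the Xavier (Glorot) scale `sigma = sqrt(2/(fan_in + fan_out))`,
  with the sign taken from the association direction. Only the top 35% of
  surviving edges per layer (by absolute weight) stay unmasked; pairs that
  are not even nominally significant (p ≥ 0.05) are zeroed beforehand, since
  masking is meant to act on the significance-restricted edge set. The 19
  phenotype→disease edges carry no association information and are drawn
  fresh from the Xavier normal.

### The inverse transform, in detail

The exported `pvalueToWeight()` is the closed form
`sign * sigma * qnorm(1 - p/2)`: strictly decreasing in p, zero at p = 1, and
mapping uniformly distributed p-values to half-normal weight magnitudes with
scale sigma. `buildModel()`, however, defaults to a *rank-based* variant
(`weightTransform = "rank"`): within each layer the p-values are first mapped
to mid-rank quantiles `u = (rank - 0.5)/m` and then through the same closed
form. The reason is numerical. At a few hundred multilevel samples the
strongest association p-values underflow toward machine minimum, and the
direct closed form then produces weights of ten or more sigma; with such
weights every downstream tanh saturates to exactly ±1 in double precision,
the gradient factor `1 - tanh²` is identically zero, and training cannot move
the network at all. The rank variant keeps exactly what the initialization is
meant to achieve — weights that *are* Xavier-distributed and ordered by
significance — while bounding magnitudes near 3 sigma. The direct form
remains available via `weightTransform = "direct"`.

### Training

Binary cross-entropy is minimized with ADAM (β₁ = 0.9, β₂ = 0.999,
ε = 1e-8) at the tuned defaults: learning rate 0.005, batch size 250, 750
epochs, evaluated by stratified 10-fold cross-validation and, for headline
accuracy, averaged over 100 trained models (`trainConfig()`). There are no
bias terms anywhere: the fully connected comparator over layers
138/67/42/19/1 then has exactly 138·67 + 67·42 + 42·19 + 19 = 12 877 edges,
which the bias-free parameterization reproduces. Gradients are multiplied by
the masks every step and weights re-masked after each update, so
`W ⊙ (1−M) = 0` holds at every epoch — a tested invariant. Training is
single-threaded and seed-deterministic.

### Interpretation

Impact scores linearize the network: each node is treated as an additive
combiner and the activation functions are deliberately ignored, so the score
of a SNP is `|row of (W1⊙M1)(W2⊙M2)(W3⊙M3)w4|`. The package ships both the
matrix-product implementation and an explicit path-enumeration reference; the
suite verifies their equivalence to 1e-9 on a thousand random models. Scores
use trained weights by default (interpretation follows training). Mediator
modules keep the top 10% of absolute trained weights *globally* across the
three inter-layer matrices — the model-wide reading of "top weights" — and
then retain exactly the nodes and edges with a surviving directed path into
the anchor phenotypes.

### Combination screening

All `Σ C(5,k)·3^k = 1023` genotype-state combinations of the five
highest-impact SNPs are enumerated (states 0/1/2 = homozygous reference /
heterozygous / homozygous alternative). A sample carries a combination when
it matches every assigned state exactly; samples with a missing genotype at
an assigned SNP have undefined carrier status and are excluded from both
numerator and denominator. A combination passes when precision strictly
exceeds 0.6 *and* the hypergeometric upper-tail p-value (population = all
samples, successes = all patients) is strictly below 0.05; ties fail. No
multiple-testing correction is applied across the 1023 combinations,
matching the original protocol. Passers are re-evaluated on an independent
cohort; a combination whose holdout precision falls below the holdout base
rate is labelled *de-enriched*, and one with no holdout carriers is flagged
rather than scored. Single-SNP state markers screened with identical
statistics provide the control comparison.

## The synthetic-data generator

The multilevel cohorts this method was designed for are access-restricted,
so the package includes a first-class generator (`synthConfig()`,
`genMultilevel()`, `genEndToEnd()`) with planted, recorded ground truth.
Desk-scale defaults mirror the study conditions: 57 multilevel samples, 138
risk SNPs, pools of 67 isoforms / 42 markers / 19 phenotypes, 7300
end-to-end samples; everything is configurable.

* Genotypes are Binomial(2, maf) — Hardy–Weinberg equilibrium — with MAFs
  drawn uniformly from [0.1, 0.5]: GWAS risk SNPs are, by ascertainment,
  common variants. There is no linkage disequilibrium, imputation error or
  population stratification.
* Isoforms are linear in genotype (planted per-allele effects in noise-SD
  units, default 2) plus small age/sex effects and unit Gaussian noise.
  Markers mix a tanh of the standardised isoform signal — a monotone
  nonlinearity, so the rank-based upper-layer tests face a genuinely
  non-Gaussian dependency — and phenotypes mix standardised markers.
* Every feature also loads (with random sign) on a shared sample-level
  latent factor (`latentSd`, default 0.5). Real expression and
  neuropathology panels are pervasively correlated; without this term the
  only significant upper-layer edges are the planted ones, and the top-35%
  rule would then discard most planted paths purely because the null is
  unrealistically clean. The factor is independent of genotype, so
  genotype-feature null calibration is untouched.
* Planted structure is a dense block: five causal SNPs (the first,
  "dominant", feeds two isoforms), whose isoforms all feed a small set of
  markers, which all feed a few phenotypes; the disease liability sums the
  standardised planted phenotypes and the label is
  Bernoulli(sigmoid(liability + intercept)). The dense block reflects that
  multilevel assays are redundant readouts of the same underlying
  processes: signal accumulates coherently across readouts while per-feature
  noise does not, giving the genotype a realistic share of liability
  variance for a highly heritable disease. The intercept defaults to
  auto-calibration at 50% prevalence (case-control balance).
* Diagnosis appears both as the generated label and as a covariate in the
  multilevel table, mirroring the case/control usage of the original
  design.

What passing on these data does **not** show: robustness to LD between
candidate SNPs, to confounded expression batches, to missing genotypes at
scale, or to phenotype-driven reverse causation — none of which the
generator emulates.

## Numerical and design choices

* **Expression-PC adjustment.** The eQTL protocol adjusts for hidden
  expression confounders (surrogated here by principal components of the
  isoform matrix, `nPCs`). The default is 0: with a desk-scale isoform pool
  (tens of features rather than tens of thousands) the top PCs coincide
  with the strongest genotype-driven expression directions, and
  residualising against them removes the associations being tested. For
  transcriptome-scale tables, set `nPCs` to e.g. `min(15, n - 10)`.
* **Disease-profile covariate.** The multilevel covariate table carries a
  single binary diagnosis column by default; `batchAssoc()` accepts any
  covariate labels, so a multi-level factor can be supplied as dummy
  columns.
* **Keep-count rounding** is `ceiling(keepFraction · E)` over the E edges
  with nonzero initial weight; ties in |weight| break by (row, column)
  lexicographic order. Both choices are arbitrary but deterministic and
  tested.
* **Degenerate inputs.** Pairwise `linearAssoc()`/`kendallAssoc()` raise
  errors on constant predictors and singular designs; the batch engine
  instead records statistic 0 / p 1 for monomorphic SNPs so one bad column
  cannot abort a 9000-pair table. Exact-zero p-values from noiseless fits
  are clamped to the smallest positive double so p stays in (0, 1].
  `precisionScore(0, 0)` returns a flagged NA ("no carriers") rather than
  an error.
* **Determinism.** Every stochastic step (genotype draws, output-layer
  Xavier init, batch shuffling, fold assignment) runs under an explicit
  seed through an RNG-state-preserving helper; reruns with the same
  configuration are byte-identical, including serialized model JSON (17
  significant digits, bit-exact round trip).
* **Problem sizes.** The test-suite and acceptance runs use 500 multilevel /
  5000 end-to-end samples with planted effects of 1.5–2 SD; recovery loops
  use narrower layer pools (40/20/10/6) and shortened training (100–200
  epochs, 5 folds), which the signal strength makes sufficient. These are
  the package's verification scales; the defaults above remain the tuned
  full-scale values.

## Known limitations

* The published headline accuracies and the data-derived architecture
  (67/42/19 selected nodes, 1192 surviving edges) depend on restricted
  cohorts and are documented, not reproduced; the surviving-edge count in
  particular depends on an unpublished pre-mask significance rule, exposed
  here as `pCutoff`.
* The hypergeometric p-values of the published combination table require
  unpublished population totals and cannot be recomputed.
* Impact scores ignore the activation nonlinearities by construction; they
  are path-attribution summaries of the linearized network, not exact
  gradients of the trained classifier.
* The Kendall batch engine is quadratic per pair; at transcriptome scale a
  dedicated tau implementation would be preferable.
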
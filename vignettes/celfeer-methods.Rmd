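---
title: "Read-resolution deconvolution of cfDNA methylation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-resolution deconvolution of cfDNA methylation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cell-free DNA (cfDNA) in plasma is a mixture of short fragments released by
dying cells across the body. Because DNA methylation is laid down in a cell
type specific way, the methylation pattern on each sequenced fragment carries
information about the tissue that released it. Deconvolution asks: given
bisulfite reads from one or more cfDNA samples and reference methylomes for a
panel of cell types, what fraction of the cfDNA came from each cell type?

Most methods summarise methylation per CpG site (beta values) and lose the
haplotype information within a read. This package instead works at the
resolution of individual reads: a read covering `k >= 3` CpGs is summarised by
its *read average* (methylated CpGs divided by `k`), discretised to the five
bins `{0, 0.25, 0.5, 0.75, 1}` and one-hot encoded. Summing the one-hot
vectors of all reads whose midpoint falls into the same marker region gives,
per individual `n` and region `m`, a vector of five counts — the
`ReadCountTensor`. The reference panel is encoded the same way per cell type
(`ReferenceTensor`).

## The model

Let `alpha[n, t]` be the fraction of individual `n`'s cfDNA originating from
cell type `t`, and `beta[t, m, i]` the probability that a read from cell type
`t` at region `m` shows read-average bin `i`. Each input read carries a latent
cell type of origin `z`; given `z = t` its bin is categorical in
`beta[t, m, ]`, and `z` itself is categorical in `alpha[n, ]`. Reference
counts are multinomial draws from `beta[t, m, ]` at the observed reference
depth, so the reference informs `beta` but does not fix it — reference panels
are imperfect and the input data can correct them.

The EM algorithm alternates:

* **E step** — posterior probability that a read with bin `i` at region `m`
  came from cell type `t`:
  `p[n,t,m,i] = alpha[n,t] beta[t,m,i] / sum_k alpha[n,k] beta[k,m,i]`
  (`eStep()`).
* **M step** — closed-form updates: `alpha[n,t]` is the posterior-weighted
  share of individual `n`'s reads assigned to `t`; `beta[t,m,]` pools the
  posterior-weighted input counts with the reference counts and renormalises
  (`mStep()`). Following the model's complete-data likelihood, in which the
  reference term appears inside the sum over individuals, the reference
  counts enter the pooled update with weight `N` (the number of individuals).

Because EM only finds local optima, `fitCelfeer()` runs the optimisation from
`nRestarts = 10` independent random initialisations (proportions uniform and
normalised; bin distributions from the reference fractions) and returns the
restart with the highest log-likelihood.

An *unknown* cell type — one present in the cfDNA but absent from the
reference — is modelled by an all-zero reference row (`maskUnknowns()`). Its
bin distributions initialise to the uniform `{0.2, ..., 0.2}` and are then
estimated from the input alone.

### The likelihood used for restart selection and monotonicity

Two candidate criteria exist: the EM objective `Q` (the expected
complete-data log-likelihood, exposed as `expectedLogLikelihood()`) and the
marginal observed-data log-likelihood. We select restarts and report
`logLik()` on the **marginal** likelihood (input mixture term plus the
`N`-weighted reference multinomial term, including its data-only coefficient
computed once per fit). The reason is structural: EM guarantees the marginal
likelihood is non-decreasing across iterations, whereas `Q` evaluated at each
iterate's own posterior also contains the posterior entropy and need not be
monotone. The test suite asserts this monotonicity on 100 random instances.

### The CpG-count baseline

The beta-value model (`fitCelfie()`) is the two-category special case of the
same likelihood: every CpG measurement on a read is Bernoulli in the cell
type's methylation fraction and the reference counts are binomial. Both
models therefore share one EM core, and on data whose reads show only
averages 0 or 1 the two produce identical proportion estimates (tested to
1e-6). A non-negative least squares baseline (`nnlsDeconvolve()`, solved with
`pracma::lsqnonneg` and renormalised to the simplex) completes the
comparison set.

## Tunable parameters

* `nRestarts` (default 10) — EM restarts; restart `r` uses `seed + r`, so a
  whole multi-restart fit is reproducible from one master seed.
* `maxIter` (default 1000) and `tol` (default `1e-4`) — convergence is
  declared when the largest absolute change of any proportion between
  consecutive iterations falls below `tol`. The default matters: proportions
  move in small per-iteration steps even far from the optimum, and a looser
  `1e-3` stop was measured to leave the CpG-count model at roughly a third of
  its converged accuracy on the generated-data design (it stops after ~15 of
  the ~450 iterations actually needed). `1e-4` recovers the converged
  solution at about half the cost of `1e-5`, whose further accuracy gain is
  negligible.
* probability floor `1e-10` — after every update each bin probability is
  floored and the 5-vector renormalised, so the posterior stays defined when
  a bin with observed reads has zero estimated probability. The perturbation
  is orders of magnitude below all reported quantities.
* `minCpgs = 3` — reads with fewer CpGs carry too little haplotype
  information and are discarded, matching standard read-level practice.
* Bin midpoints (`0.375` etc.) round *up* to the higher bin — an arbitrary
  but deterministic tie rule.
* Reads spanning two windows are assigned by their midpoint (left window on
  an exact boundary): each read must count exactly once because the model
  treats reads as units.

## Marker selection

Markers are 500 bp windows in which one cell type is hypomethylated below
every other. Per window and cell type, `summarizeWindows()` computes the mean
of read averages and the read depth (or pooled CpG counts in `"count"` mode);
`markerDistance()` is `min(others) - own`, positive only for the uniquely
least methylated cell type. `selectMarkers()` keeps windows where every cell
type has at least one read, the lower-median depth across cell types and the
candidate cell type's own depth reach the threshold (20 in read-average mode,
150 in count mode — count-mode depths are CpG measurements, hence the larger
scale), ranks by distance (ties broken by genomic position for
determinism), removes any window ranked in the top 150 of two or more cell
types, and returns the top 100 per cell type. With the hypomethylation filter
on, a window can have a positive distance for at most one cell type, so the
exclusivity step is a safeguard that mostly matters when the filter is
disabled for exploration.

## What the simulations emulate

`simulateGeneratedData()` draws data exactly under the model: uniform
normalised proportions, per-region bin distributions, Poisson(10) read depth,
categorical read origins and bins, multinomial reference counts. The true bin
distributions are symmetric Dirichlet(1) draws — the maximum-entropy analogue
of the uniform methylation fractions used for the CpG-count generator
(`simulateCelfieData()`), which has no canonical read-average counterpart;
the concentration is exposed in the API. Two derived designs reproduce the
benchmark protocols: `simulateTwoGroupRare()` (a cell type at proportion 0.01
in five individuals and 0 in five others, nine background types uniform on
[0.5, 1], all jointly normalised; the rare type is the first) and
`simulateUnknownExperiment()` (the last cell type's reference zeroed, its
true proportion Normal(0.2, 0.1) clipped to [0, 1]; the nine known
proportions are scaled to the remaining mass so the unknown's distribution is
exactly the stated clipped normal).

Read-level designs are served by `simulateReads()` (reads placed uniformly in
regions, CpG states Bernoulli in a per-region methylation probability),
`mixReads()`/`mixCounts()` (coverage normalisation to a common total, scaling
by mixing proportions with stochastic rounding — floor plus a Bernoulli on
the fractional part, which keeps counts integral without biasing the
expectation — and pooling), and `injectNoise()` (independent CpG state flips
with probability `p`).

These generators deliberately omit several features of real WGBS data:
correlated methylation between neighbouring regions, fragment-length and GC
biases, bisulfite conversion failure beyond the symmetric flip model, SNPs
and mapping artefacts. Passing the simulation benchmarks therefore shows the
estimator is correct *under its own assumptions* and robust to symmetric
noise; it does not certify performance on real plasma data.

## Benchmark protocols and problem sizes

The packaged benchmarks (`runGeneratedBenchmark()`, `runUnknownBenchmark()`,
`runRareBenchmark()`, `runNoiseBenchmark()`) use the published design sizes:
50 replicates of 25 cell types x 6000 regions x 1 individual at Poisson(10)
depth for the generated-data correlation; 1000 regions x 10 cell types x 10
individuals at depth 10 for the masked-unknown RMSE; 50 replicates of the
two-group rare design; and a 5-cell-type, 150-window, coverage-30 read-level
mixture for the noise sweep (8 replicates per flip probability in
`{0, 1/100, 1/30, 1/10}`), chosen as the smallest design in which the
five cell types are comfortably identifiable so that the noise effect, not
sampling noise, dominates the comparison.

Two empirical observations from these benchmarks are worth recording. First,
with a converged EM the generated-data correlation sits near 0.94-0.96 for
both models — in line with the original beta-value EM publication's reported
0.96 +/- 0.01 on the equivalent design — and the estimates are essentially
limited by the information in ~6 x 10^4 reads. Second, when a cell type is
masked from the reference its proportion is systematically over-estimated
(the free component can fit the pooled input distribution better than any
mixture of reference-anchored components); the same inflation is reported for
real-data mixtures in the literature. Both behaviours are properties of the
maximum-likelihood formulation, not of this implementation: the test suite
verifies the optimiser against an exhaustive grid-search oracle on small
instances, and fits the identical design with the reference unmasked, which
recovers the same cell type's proportions near the sampling limit.

## Known limitations

* Point estimates only: no uncertainty quantification on the proportions.
* The unknown-cell-type mechanism inherits the inflation bias above; treat
  absolute unknown proportions as upper bounds.
* Read pairs are treated as independent reads unless merged upstream, and
  methylation calls are assumed collapsed to CpG units (strand ignored).
* BAM parsing and bisulfite alignment are out of scope; inputs are the
  plain-text read-level TSV or pre-binned count TSVs described in the README.
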
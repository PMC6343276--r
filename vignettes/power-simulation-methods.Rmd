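---
title: "Simulating type I error and power for rare-variant burden and SKAT tests"
author: "rvpower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating type I error and power for rare-variant burden and SKAT tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvpower)
```

## The question the package answers

Region-based rare-variant association tests pool the variants of a gene-like
region ("bin") into a single test because individual rare alleles carry too
little information to test one at a time. Two families dominate practice:
*burden* tests, which collapse the bin into one weighted allele-count score
per individual and regress case status on it, and *dispersion* tests such as
SKAT, which score the distribution of per-variant effects through a weighted
kernel. Their operating characteristics under **unbalanced** case-control
designs — a few hundred cases against tens of thousands of biobank controls,
the typical PheWAS situation — differ sharply from the balanced designs most
power studies assume.

`rvpower` implements a complete, seed-reproducible simulation study of this
question: a genotype simulator with exact prevalence calibration, both tests
with pooled Madsen-Browning weighting, and a scenario-grid engine that
estimates type I error and power over balanced and unbalanced designs.

## The data-generating model

One simulated dataset is a bin of `p = 143` independent rare loci (the mean
rare-locus count of a gene-sized bin in large exome panels). Locus `j` gets a
minor allele frequency `q_j` drawn from a truncated power-law density
proportional to `q^(-shape)` on `[0.0015, UB]`, `UB` either 0.01 or 0.05.
Genotypes are Hardy-Weinberg, `x_j ~ Binomial(2, q_j)`, independent across
loci (no linkage). Disease risk follows a logistic penetrance model

    logit P(case | x) = alpha + sum_j beta_j x_j

with per-locus log odds ratios `beta_j`. Effect scenarios:

* **null** — all `beta_j = 0` (type I error);
* **uniform_or** — 10 loci, placed uniformly at random, each with odds
  ratio 2.5;
* **mixed_low / mixed_moderate / mixed_high** — 10 loci, half carrying one
  of five risk odds ratios, half the five reciprocal protective values
  (`mixedOddsRatios()` lists them), shuffled onto the chosen loci.

The intercept `alpha` is not free: it is calibrated so that the *population*
prevalence `E[plogis(alpha + sum_j beta_j x_j)]` equals 5% exactly.
`calibrateIntercept()` computes that expectation in closed form by
enumerating the Hardy-Weinberg configurations of the (at most 15) disease
loci — equal effects collapse to a convolution over the total disease-allele
count, unequal effects use the full `3^d` expansion — and solves for `alpha`
by root finding, achieving `|prevalence - 0.05| <= 1e-6`. A deterministic
evaluator was chosen over stochastic search because it makes calibration
testable to tolerance; `monteCarloPrevalence()` remains as an independent
cross-check and as the evaluator beyond 15 disease loci.

Cohorts are ascertained retrospectively: individuals are drawn from the
population model and kept while their group's quota (cases or controls) is
unfilled, until both quotas are met. At 5% prevalence a case costs about 20
population draws. Since the neutral loci are independent of disease status,
the implementation draws them only for retained individuals — the sampled
law is identical, and a 3000-case/10,000-control dataset simulates in well
under a second. A draw cap (default `1e7`) turns misconfigured prevalence
into an explicit error rather than a hang.

### What the generator does and does not emulate

The spectrum stand-in and independence assumptions matter when reading the
results. The generator emulates: rare-variant frequency spectra bounded
away from zero (lower bound 0.0015 reflects the resolution of frequency
assignment in large panels), fixed-quota case-control ascertainment,
complete data, and region sizes typical of gene bins. It does **not**
emulate linkage disequilibrium, haplotype structure, covariates, population
stratification, genotyping error, missingness, or the exact empirical
MAF histogram of any particular exome resource. Passing tests therefore
demonstrate the statistical behavior of the tests under a clean idealized
rare-variant architecture, not performance on any specific real cohort.

### The spectrum shape default

The real study this design reflects drew frequencies from a proprietary
exome panel that is not redistributable, so the package substitutes a
parametric family. `shape = 1` — the neutral site-frequency-spectrum decay,
density `∝ 1/q` — is the default: it is the standard population-genetic
reference spectrum, and under it the package's simulated landscape
reproduces the documented benchmark thresholds (SKAT ≥ 90% power at a
balanced total of 4000; both tests < 50% at a total of 1000; SKAT ≥ 90% at
500 cases vs 10,000 controls; burden ≥ 90% at 3000/10,000 and 7000/7000;
balanced type I error ≤ 0.1). Steeper shapes (2–3) concentrate mass near
0.0015 and lower power; the parameter is exposed everywhere
(`sampleMafSpectrum()`, `Scenario(mafShape =)`) for sensitivity analyses.

## The two tests

Both tests share the pooled **Madsen-Browning weights**
`w_j = 1 / sqrt(n q_hat_j (1 - q_hat_j))` with
`q_hat_j = (c_j + 1) / (2n + 2)`, where `c_j` is the minor-allele count over
*all* `n` individuals. Two deliberate choices:

* **Pooled, not controls-only.** The original burden-weighting proposal
  estimated frequencies from controls alone; pooling cases and controls
  makes the weights — and hence both tests — exactly invariant under
  exchanging case and control labels, so a 100-case/1000-control design and
  its 1000/100 mirror give bit-identical p-values. (Internally both tests
  orient the phenotype to its minority class before fitting — a
  deterministic canonicalization that turns the mathematical symmetry into
  an exact floating-point identity.) The acceptance suite asserts this
  invariance.
* **Pseudocount 1** keeps weights finite at monomorphic loci. Both are
  configurable (`mbWeights(pseudocount =)`).

The **burden test** regresses case status on the collapsed score
`s_i = sum_j w_j x_ij` by logistic regression and refers the
likelihood-ratio deviance to chi-square with 1 df. The LRT was preferred
over a Wald test because it is better behaved for skewed rare-variant
scores and under near-separation. Degenerate inputs are reported, not
failed: a zero-variance score gives `p = 1` with `converged = FALSE`;
boundary fitted probabilities (complete separation) cap the statistic at
the last IRLS iterate and clear the flag.

The **SKAT test** computes `Q = (y - mu)' G W^2 G' (y - mu)` under the
intercept-only logistic null (`mu` = sample case fraction; no covariates
are simulated, so none are modeled). Its null law is the weighted
chi-square mixture with weights the nonzero eigenvalues of `W G' P0 G W`,
`P0` the null-model projected variance. Eigenvalues below `1e-10` of the
largest are discarded as numerically null directions.

### Mixture p-value numerics

No mixture-distribution library is assumed: `pMixtureChisq()` inverts the
characteristic function (Imhof-type oscillatory integral) via adaptive
quadrature with an absolute accuracy target of `1e-6`, and falls back to a
moment-matched noncentral chi-square (Liu-type, skewness/kurtosis matched)
whenever inversion fails, reports insufficient accuracy, or lands outside
`[0, 1]` — which is the deep-tail regime where inversion is unreliable and
where the distinction is immaterial for rejection counting at
`alpha = 0.05`. Each result records which route produced it. Unit tests pin
the inversion against closed forms (one eigenvalue = scaled chi-square(1);
`k` equal eigenvalues = scaled chi-square(k)) and against direct Monte
Carlo simulation of the mixture.

### Finite-sample behavior, on purpose

The asymptotic mixture null assumes normally distributed score vectors. At
small case counts relative to controls, the score distribution is skewed
and the analytic p-values deviate from the exact permutation law — this is
precisely the mechanism behind SKAT's inflated type I error in strongly
unbalanced designs, which is a central *finding* of the study design, not a
bug. The package therefore implements standard (unadjusted) SKAT, and
`permutationPvalue()` provides the exact-null oracle for quantifying the
deviation. At `n = 30` the analytic and permutation p-values differ by
roughly 0.03 systematically (partly the finite-population variance factor
`n/(n-1)`, partly higher moments); by `n = 200` the gap is within Monte
Carlo noise plus an `O(1/n)` allowance, which is what the test suite
asserts.

## The study engine

`Scenario()` captures one design cell; `scenarioGrid()` enumerates the full
published design: balanced totals
20–20,000 (12 cells), case counts 10–7000 against 10,000 controls and
10–1000 against 30,000 controls (21 unbalanced cells), crossed with both
frequency bounds and the null/uniform effect models, plus the three mixed
models at the two reference designs (2000/2000 and 200/10,000).

`runDataset()` is one pipeline pass — spectrum, effect model, calibration,
ascertainment, weighting, tests — fully determined by
`(scenario, datasetSeed)`. The spectrum and the disease-locus placement are
redrawn per dataset, so replicate variability includes region-to-region
heterogeneity; a fixed-region analysis can be built directly from the
lower-level functions if a variance decomposition is wanted.

`estimateRejectionRate()` runs `nDatasets` datasets and reports the
proportion with `p <= alpha` per test, retaining the per-dataset p-value
table so rates can always be recounted. `runReplicates()` repeats this
`nReplicates` times — the full-size profile is 1000 datasets × 30
replicates per cell; the `"ci"` profile (200 × 5) is for interactive use —
and `summarizePower()` produces the long replicate table and
quartile summaries that the study's boxplots are drawn from, orderable by
case:control ratio or by case count.

Per-dataset seeds are derived by a 32-bit FNV-1a hash of
`(baseSeed, canonical scenario string, replicate, dataset)`, so any single
dataset can be reproduced in isolation from the persisted seed manifest,
and replicates are independent by construction.

The test suite and the acceptance script run this engine at reduced
budgets — 120–300 datasets per power cell, 1000–2000 for type I error —
sized so that a binomial standard error of 2–3% leaves the thresholds
clearly decidable; the full 1000 × 30 profile is a batch job.

## Numerical and design decisions worth knowing

* **Calibration bracket**: prevalence is strictly increasing in `alpha`,
  and shifting `alpha` past the extreme linear-predictor offsets brackets
  the target analytically, so root finding cannot escape the bracket;
  non-convergence to `1e-6` is an error, never silent.
* **VCF conventions**: simulated cohorts export as VCF v4.2 on
  pseudo-chromosome "1", positions `1..p`, `REF=A`, `ALT=C`, the true
  simulated frequency in `AF`; ALT is the minor allele *by construction*,
  and the reader errors (rather than silently flipping) if a file violates
  that. VCF is 1-based; internal matrices are plain 0-based R matrices;
  conversion happens only at this boundary.
* **Monomorphic bins** (possible at tiny cohorts and rare spectra) give
  `p = 1` with `converged = FALSE` for SKAT rather than an error, so grid
  sweeps over very small samples complete.
* **Missing features**: no covariate adjustment, SKAT-O, small-sample
  adjusted SKAT, quantitative traits, or LD — out of scope by design.

## Known limitations

Power and type I error estimates inherit the stand-in spectrum: absolute
power levels shift with `shape`, though the qualitative contrasts (SKAT vs
burden, balanced vs unbalanced, case-count-driven behavior) are stable
across the shapes we examined. Independence across loci overstates the
effective number of independent variants relative to real LD structure.
And the burden test's power depends strongly on the fraction of causal
loci in the bin (10/143 here); bins with denser signal favor the burden
test more than these simulations suggest.
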
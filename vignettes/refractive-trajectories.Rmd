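---
title: "Regional rare-variant enrichment and gene-by-reading trajectory models"
author: "myodev"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional rare-variant enrichment and gene-by-reading trajectory models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myodev)
```

## The scientific problem

Myopia (near-sightedness) develops during childhood as the eye's axial
growth overshoots its optical power; spherical equivalent refraction,
measured in diopters (D), drifts negative over the school years in children
who become myopic. Two kinds of evidence implicate both genes and visual
environment: low-frequency regulatory variants near candidate genes show
weak single-SNP association signals, and time spent on near work (reading)
is a reproducible environmental risk factor. `myodev` packages the analysis
chain needed to study the interplay of the two:

1. a **single-SNP dosage regression scan** across a genomic region, with
   QQ-plot computation;
2. a **phenotype-permutation regional test** that converts the scan into a
   single region-level empirical p-value, using either the minimum p or a
   low-percentile p (an "excess of low p-values" statistic) — the natural
   inference when SNPs in a linkage-disequilibrium (LD) block are too
   correlated to count as independent tests;
3. a **Kolmogorov–Smirnov region comparison** for the summary-statistics-only
   setting where raw genotypes are unavailable (p-values inside a candidate
   region versus its flanks, or versus the uniform distribution);
4. a **linear mixed model** for longitudinal refraction trajectories with a
   genotype × reading × age interaction;
5. **cross-sectional gene–environment models** (logistic odds ratios for
   myopia, incremental variance explained for refraction);
6. a **two-class expression ranking metric** (signal-to-noise) for
   experimental myopia expression data.

Because individual-level cohort data of this kind are not publicly
deposited, the package carries a first-class synthetic cohort generator
that emulates the relevant statistical structure, and every stage is
validated against independent oracles on generated data.

## The generative model

The cohort generator is the reference description of the data the analyses
expect.

**Genotypes.** An LD block is simulated by a Gaussian copula: each
haplotype draws a latent AR(1) Gaussian vector across SNPs (adjacent-SNP
correlation `ld_rho`, default 0.8) and carries the effect allele where the
latent value falls below the allele-frequency quantile; dosage is the sum
of two haplotypes. This is deliberately minimal — one parameter, a
qualitatively correct correlated block — and makes no claim to
coalescent or recombination-map realism. The default block contains 30
SNPs with a risk variant of effect-allele frequency 0.01 in the middle,
so a cohort of a few thousand subjects contains on the order of 2%
carriers, matching the regime where single-SNP evidence is weak and
regional aggregation matters.

**Exposures.** Time reading is binary ("low" = 0 reference, "high" = 1)
with high-prevalence 1686/4461 ≈ 38% and missingness 739/5200 ≈ 14%,
reproducing the reported low/high/missing split of the motivating cohort;
time outdoors uses its analogous 2145/2349/706 split. Questionnaire text
responses are dichotomized by `code_reading()` / `code_outdoors()`:
"1–2 hours" and "3 or more hours" are high, "None at all" and "1 hour or
less" low.

**Trajectories.** For subject $i$ at visit $j$ with centered age
$a = \mathrm{age} - 11.5$:

$$
y_{ij} = \beta_0 + \beta_1 a + \beta_2 a^2 + \beta_3 a^3
 + \gamma_g g_i + \gamma_{ga} g_i a + \gamma_r r_i + \gamma_{ra} r_i a
 + \gamma_{gr} g_i r_i + \gamma_{gra} g_i r_i a + \beta_s s_i
 + b_{0i} + b_{1i} a + \varepsilon_{ij},
$$

with $(b_{0i}, b_{1i}) \sim N(0, G)$, $G = \begin{pmatrix} g_{00} & g_{01}
\\ g_{01} & g_{11} \end{pmatrix}$ positive semidefinite, and
$\varepsilon_{ij} \sim N(0, \sigma^2_\varepsilon)$. $g_i$ is carrier
status (rare homozygotes recoded to heterozygote by
`recode_rare_homozygotes()`, since a variant at frequency 0.01 yields
essentially no homozygotes), $r_i$ the binary reading exposure, $s_i$ sex.

Visits target ages 7.5, 10.5, 11.5, 12.5, 15.5 years with Gaussian jitter
(SD 0.15 y — ages are "approximately" the clinic targets, never exact);
each subject attends 3, 4 or 5 visits with probabilities 833/5200,
1696/5200, 2671/5200, the printed visit-count mix; dropped visits are
chosen uniformly at random (which visits were missed is not reported
anywhere, so a completely-at-random drop is the neutral stand-in).

Default coefficients describe a mildly myopizing cohort: intercept +0.3 D
at age 11.5, a slow cubic myopic drift, reading × age divergence
−0.10 D/yr, genotype × reading × age −0.06 D/yr, random-intercept variance
1.2 D², slope variance 0.02 D²/yr², residual 0.15 D². These magnitudes
were fixed once as field-realistic values: population SD of childhood
refraction is near 1–1.5 D and is dominated by stable between-subject
differences, while annual within-subject change is a fraction of a
diopter. What the generator does *not* emulate: measurement error specific
to non-cycloplegic autorefraction, informative missingness, LD decay with
physical distance, relatedness, or population structure. Passing tests on
this synthetic cohort therefore demonstrate the correctness and
calibration of the estimators, not robustness to those real-data
complications.

## The regional permutation test

Within a region the scan regresses phenotype on each SNP's dosage plus
covariates (OLS, two-sided t reference). A transparent OLS t-test was
chosen over any particular association tool's score test: with the
permutation layer on top, regional inference is distribution-free anyway.
Missing dosages are handled per SNP by complete cases so each SNP's `n`
stays honest.

The permutation test reassigns phenotypes to subjects by sampling without
replacement (covariates travel with the phenotype owner — the scheme
permutes the phenotype vector only, the plain phenotype-permutation
design; a Freedman–Lane residual scheme would be the natural extension but
is deliberately not the default). After each of $B$ permutations the whole
scan is recomputed and the summary statistic recorded; we report
$\hat{p} = (r + 1)/(B + 1)$ with $r$ the count of permutation statistics
at least as extreme (ties count as extreme — the conservative direction; a
hairline $10^{-9}$ relative tolerance keeps permutations that merely
reorder floating-point sums classified as ties). The add-one estimator
never returns 0 and is valid by construction. Two statistics are exposed,
because a single strong SNP and a diffuse excess of low p-values are
different phenomena:

* `min_p` — the region's smallest single-SNP p;
* `percentile_p` — the $\lceil qm \rceil$-th smallest of $m$ p-values
  (default $q = 0.05$, the "5th percentile p-value"; an order statistic,
  no interpolation).

For $n \le 8$ subjects the test can enumerate all $n!$ permutations and
return the exact proportion; this exhaustive mode is the package's own
correctness oracle. Internally, permutation scans use Frisch–Waugh
residualization (phenotype and dosages residualized against the covariate
block once, then each SNP's t from a single cross-product), which is
algebraically identical to refitting each model — the equality is itself
under test — and makes a 1000-permutation scan of thousands of subjects a
matter of seconds.

When only summary statistics are available, `split_region_pvalues()`
partitions SNPs into the closed candidate region versus its ±100 kb
flanks, and `ks_region_comparison()` applies the two-sample
Kolmogorov–Smirnov test (asymptotic p; small groups are flagged below
n = 10 rather than silently trusted), or a one-sample comparison against
U(0,1).

## The trajectory mixed model

`fit_lmm()` is this package's own implementation, written for exactly the
model family above: fixed effects from the trajectory vocabulary, random
intercept and age slope per subject. The marginal covariance per subject
is $V_i = \sigma^2 (I + Z_i \Psi Z_i^\top)$ with $\Psi$ the relative
random-effect covariance. The optimizer works on the log-Cholesky factor
of $\Psi$ (three unconstrained parameters): $\beta$ is profiled out by
generalized least squares and $\sigma^2$ analytically, so one objective
evaluation costs a handful of $2 \times 2$ closed-form Woodbury
operations, vectorized across subjects from cross-products computed once.
Estimation is REML by default for reporting; ML for likelihood-ratio
comparison of fixed-effect structures (`lrt()` refuses REML fits, whose
restricted likelihoods are not comparable across fixed-effect designs).
Optimization is quasi-Newton (BFGS) with relative tolerance $10^{-8}$ and
a cap of 500 iterations, restarted from alternative initial values and
polished by Nelder–Mead, with convergence reported honestly in the fit
object. The log-Cholesky parameterization keeps $\hat{G}$ positive
semidefinite by construction, including at the variance boundary.
Wald tests use the standard-normal reference; no Satterthwaite or
Kenward–Roger degrees-of-freedom refinement is attempted, and the
documentation says so — with thousands of subjects the difference is
immaterial, at a few dozen subjects the Wald p-values are anti-conservative.

Sex is available as a term but excluded by default (in the motivating
analyses it was not associated with refraction and was dropped);
`include_sex = TRUE` restores it. Subjects missing a covariate required by
the requested terms are excluded listwise with logged counts, mirroring
the analysis-set bookkeeping (a full model loses the
reading-missing subjects; a genotype-only model keeps them).

On simulated data the implementation reproduces `nlme::lme` REML
log-likelihoods and standard errors to six significant digits (this
cross-check is in the test suite; `nlme` is never the computational path).

## Cross-sectional models and the expression metric

`crosssec_gxe()` takes each subject's visit closest to the target age
(default 15.5 y, within ±1 y), classifies myopia as spherical equivalent
≤ −0.75 D (boundary inclusive; the −0.75 D convention is this package's
explicit choice — no threshold is inherited from the motivating study,
which did not print one — and it is exposed and reported loudly), and
fits logistic models with and without a carrier × exposure interaction,
reporting odds ratios with Wald 95% intervals
($\exp(\hat\beta \pm 1.96\,\mathrm{SE})$). Complete separation is
detected and flagged as non-convergence rather than returned as silently
huge coefficients. Age is not a covariate here: within one clinic visit of
a birth cohort the age spread is too narrow to matter. The linear-model
companion `incremental_r2()` reports the variance in refraction explained
by the exposure alone and the increment from adding genotype and the
interaction, on the identical case set, in percentage points.

The expression module implements the two-class signal-to-noise ranking
metric $(\mu_A - \mu_B)/(\sigma_A + \sigma_B)$ with sample SDs, after
per-gene normalization to mean 0 and SD 3 (the heat-map display
convention). The minimum-SD floor some enrichment tools apply
($\sigma \leftarrow \max(\sigma, 0.2|\mu|)$) is available behind
`sd_floor = TRUE` but off by default, since plain sample SDs are the
metric's textbook algebra; enrichment scores, NES and permutation FDR are
out of scope.

## Numerical and design choices

* **Age centering at 11.5 y** (midpoint of the visit window) keeps the
  cubic age polynomial well-conditioned; the intercept is refraction at
  11.5 y, not at birth.
* **Region intervals are 1-based and closed on both ends**, matching the
  "chr:start–end" convention of printed coordinates; a boundary SNP is
  inside.
* **Monomorphic SNPs** are skipped and logged by the scan, never fitted.
* **Collinear designs** raise an error naming the offending column.
* **Empirical p floors at $1/(B+1)$**; below B = 19 a warning notes the
  resolution exceeds 0.05. A constant phenotype short-circuits to
  $\hat p = 1$ with a warning.
* **Determinism**: every stochastic function takes a seed; the pipeline
  derives per-stage seeds from one global seed (stage index × 1000 offset)
  and records them, with the configuration hash, in a manifest sufficient
  to re-run byte-identically.
* **Serialization**: tabular outputs are tab-delimited, floats at 12
  significant digits.

## Problem sizes used in the validation suite

The test suite exercises the stack at deliberately chosen sizes: the
exhaustive-vs-Monte-Carlo oracle at 7 subjects (5,040 permutations);
permutation-test calibration on 500 null cohorts of 400 subjects × 30
SNPs at B = 199; power ordering at 3,800 subjects across planted effects
of 0, −0.3 and −0.6 D per allele; mixed-model parameter recovery on 100
cohorts of 200 subjects; likelihood-ratio calibration on 300 null
cohorts. These sizes give the binomial bands quoted in the tests their
meaning — e.g. 500 replicates at a true 5% rejection rate should land in
[0.032, 0.071] with 95% probability.

## Known limitations

* The LD model is a one-parameter copula: no distance-dependent decay, no
  haplotype blocks of varying length. In particular, a latent correlation
  of 0.8 between a 1%-frequency variant and a 25%-frequency neighbour
  translates into a small *dosage* correlation, so a single planted rare
  causal variant produces a sharp minimum-p signal rather than the diffuse
  excess of low p-values that a block of co-segregating low-frequency
  variants would give; the two regional statistics respond accordingly.
* Wald inference in the LMM uses the normal reference; small-sample
  degrees-of-freedom corrections are not implemented.
* The KS p-value is asymptotic; with fewer than ~10 p-values per group it
  is only indicative (and flagged).
* The myopia threshold is a convention, not an estimate; odds ratios move
  with it.
* Listwise deletion is the only missing-data strategy; no imputation of
  exposures.

## A minimal run

```{r example, eval = FALSE}
cohort <- simulate_cohort(n_subjects = 2000, seed = 17)
scan <- scan_region(cohort$genotypes, ...)          # see README for the
fit  <- trajectory_lmm(cohort$phenotypes,           # full worked example
                       cohort$covariates)
summary(fit)
```

The README walks through a complete example with the numbers it prints.
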
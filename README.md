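# myodev

Regional rare-variant association and gene-by-environment trajectory
modelling for refractive error.

## What this package is for

Childhood myopia emerges from an interplay between genetic susceptibility
and visual environment — above all, time spent reading. Statistically this
poses three linked problems that `myodev` addresses as one tested pipeline:

1. **Regional association with low-frequency variants.** Single SNPs at
   frequency ~1% rarely reach convincing significance on their own, and SNPs
   in a linkage-disequilibrium (LD) block are not independent tests. The
   package scans a region by per-SNP dosage regression (OLS with covariates,
   t reference), then assesses the *region* by phenotype permutation:
   subjects are reassigned phenotypes sampled without replacement, the whole
   scan is recomputed B times, and the empirical p-value
   (r + 1)/(B + 1) is reported for either the minimum p or the
   ⌈qm⌉-th smallest p (default q = 0.05, the "5th percentile p-value", a
   statistic for an *excess of low p-values*). With only summary statistics,
   a two-sample Kolmogorov–Smirnov test compares p-values inside a candidate
   region against its ±100 kb flanks.

2. **Longitudinal refraction trajectories.** Spherical equivalent (in
   diopters, D) measured over ages ~7.5–15.5 y is modelled by a linear
   mixed model with fixed cubic age effects, carrier genotype, binary
   reading exposure and their age interactions up to the 3-way
   genotype × reading × age term, plus a random intercept and age slope per
   subject:

   y_ij = β₀ + β₁a + β₂a² + β₃a³ + γ_g g + γ_ga g·a + γ_r r + γ_ra r·a
        + γ_gr g·r + γ_gra g·r·a + β_s s + b₀ᵢ + b₁ᵢ a + ε_ij,
   (b₀, b₁) ~ N(0, G),  ε ~ N(0, σ²)

   The REML/ML machinery (profiled log-Cholesky likelihood) is implemented
   in this package and cross-checked against `nlme` in the tests.

3. **Cross-sectional gene–environment models.** At a target age, logistic
   models give odds ratios for myopia (spherical equivalent ≤ −0.75 D by
   default) for carrier status, reading, and their interaction; linear
   models report the incremental variance in refraction explained by
   genotype and the interaction.

Because individual-level cohort data of this kind are not publicly
available, the package ships a first-class synthetic cohort generator
(LD-block genotypes via a Gaussian copula, questionnaire exposures with a
realistic missingness split, trajectory phenotypes from the model above)
that every stage is tested against. See the vignette
(`vignettes/refractive-trajectories.Rmd`) for the model details and design
choices.

## Worked example

```r
library(myodev)

# the default cohort: 5,200 subjects, a 30-SNP LD block with the risk
# variant (RAF 0.01) at its centre, reading exposure, 3-5 visits per
# subject over ages 7.5-15.5
cohort <- simulate_cohort(seed = 17)

# cross-sectional phenotype at the oldest visit
ph <- cohort$phenotypes
ph <- ph[abs(ph$age_years - 15.5) <= 1, ]
ph <- ph[!duplicated(ph$subject_id), ]
ix <- match(ph$subject_id, cohort$covariates$subject_id)
g15 <- cohort$genotypes
g15$dosage <- g15$dosage[ix, ]
covars15 <- cbind(age = ph$age_years, sex = cohort$covariates$sex[ix])

scan <- scan_region(g15, ph$sph_equiv_D, covariates = covars15)
scan
#> region_scan 11:129904497-129962497: 30 SNPs tested, 0 skipped
#> top SNP snp15: beta = -0.493 D (SE 0.124), p = 6.83e-05, n = 4511

perm <- permutation_region_test(g15, ph$sph_equiv_D, covars15,
                                statistic = "min_p", B = 999, seed = 17)
perm
#> regional permutation test (minimum p, B = 999)
#> observed statistic = 6.829e-05, empirical p = 0.003
```

The top SNP is the planted risk variant: each copy of its risk allele
shifts refraction at 15.5 y by about −0.5 D in this draw, and the
region-level minimum-p permutation test stays significant after
accounting for all 30 correlated tests. (The 5th-percentile statistic is
not significant here — with a single causal rare variant whose dosage is
only weakly correlated with its common neighbours, there is no diffuse
excess of low p-values; the two statistics deliberately answer different
questions.)

```r
fit <- trajectory_lmm(cohort$phenotypes, cohort$covariates,
                      model = "full", estimation = "REML")
fit$n_subjects
#> [1] 4468   # of 5,200; subjects missing the reading exposure are excluded
wald_test(fit, "genotype:reading:age")
#> $estimate          $se          $z        $p
#> -0.0133        0.0366      -0.363     0.716
```

The 3-way term estimates how much faster carriers drift myopic per year
*when they also read a lot* (generative truth −0.06 D/yr). Its Wald SE of
~0.037 D/yr shows why this single draw is inconclusive — with ~2%
carriers the interaction is at the edge of detectability at this cohort
size, which is precisely the regime the permutation and calibration
machinery in this package is built to quantify honestly.

```r
cs <- crosssec_gxe(cohort$phenotypes, cohort$covariates)
cs$logistic_main
#> logistic model, n = 3873
#>         term estimate      se     or ci_low ci_high         p
#>  (Intercept)  -0.7662 0.04383 0.4648 0.4265  0.5065 1.969e-68
#>     genotype   0.5005 0.23810 1.6500 1.0340  2.6310 3.558e-02
#>      reading   0.6814 0.06836 1.9770 1.7290  2.2600 2.118e-23
cs$r2
#> R^2 base = 0.0434 (4.34%), full = 0.0468 (4.68%), delta = 0.34 percentage points
```

Carriers have ~1.7-fold odds of myopia at 15.5 y and high readers ~2-fold
in this draw; adding genotype and the interaction to a reading-only
linear model explains an extra 0.34 percentage points of refraction
variance.

`print` methods on every object summarize what was fitted and on how many
subjects; exclusion counts are logged at each step.

A thin command-line wrapper over these functions is installed at
`inst/cli/myodev.R` (subcommands `simulate`, `scan`, `permute`, `kstest`,
`trajectory`, `crosssec`, `rank`, `run`), and `run_pipeline()` executes the
whole chain from a validated, seeded configuration with a manifest that
makes the run byte-for-byte reproducible.

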
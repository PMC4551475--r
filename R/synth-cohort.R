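#' Describe a SNP for simulation
#'
#' Builds the per-SNP metadata table used by [simulate_genotypes()]. Positions
#' must be strictly increasing and effect-allele frequencies must lie in
#' \[0, 1\].
#'
#' @param snp_id Character vector of SNP identifiers.
#' @param chromosome Chromosome label(s), recycled to the number of SNPs.
#' @param position Integer vector of 1-based basepair positions, strictly
#'   increasing.
#' @param effect_allele,other_allele Allele labels (recycled).
#' @param raf Numeric vector of effect-allele frequencies in \[0, 1\].
#' @return A `data.frame` with columns `snp_id`, `chrom`, `pos`, `a1`, `a2`,
#'   `raf`.
#' @examples
#' snp_spec(paste0("rs", 1:3), "11", c(100, 200, 300), raf = c(0.3, 0.01, 0.2))
#' @export
snp_spec <- function(snp_id, chromosome = "11", position,
                     effect_allele = "A", other_allele = "G", raf) {
  m <- length(snp_id)
  position <- as.integer(position)
  raf <- as.numeric(raf)
  if (length(position) != m || length(raf) != m)
    stop("snp_id, position and raf must have equal length")
  if (any(!is.finite(raf)) || any(raf < 0) || any(raf > 1))
    stop("raf must lie in [0, 1]")
  if (m > 1 && any(diff(position) <= 0))
    stop("position must be strictly increasing")
  data.frame(
    snp_id = as.character(snp_id),
    chrom = rep_len(as.character(chromosome), m),
    pos = position,
    a1 = rep_len(as.character(effect_allele), m),
    a2 = rep_len(as.character(other_allele), m),
    raf = raf,
    stringsAsFactors = FALSE
  )
}

#' Simulate an LD block of genotype dosages
#'
#' Draws two haplotypes per subject from a Gaussian copula with first-order
#' autoregressive correlation `ld_rho` between adjacent SNPs; each latent
#' Gaussian is thresholded at the allele-frequency quantile, and the dosage is
#' the sum of the two haplotypes. This reproduces a block of correlated SNPs
#' around a low-frequency risk variant without coalescent machinery.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param snps SNP metadata from [snp_spec()] (columns `snp_id`, `chrom`,
#'   `pos`, `a1`, `a2`, `raf`).
#' @param ld_rho Adjacent-SNP latent correlation in \[-1, 1\].
#' @param seed Integer seed; for a fixed seed the output is reproducible.
#' @return A `genotype_matrix`: list with `dosage` (subjects x SNPs matrix,
#'   values in \{0, 1, 2\}) and `snps` (the metadata).
#' @examples
#' g <- simulate_genotypes(100, snp_spec("rs1", "11", 1000, raf = 0.2), seed = 1)
#' table(g$dosage)
#' @export
simulate_genotypes <- function(n_subjects, snps, ld_rho = 0, seed = NULL) {
  stopifnot(n_subjects >= 1)
  if (!is.data.frame(snps) || nrow(snps) < 1)
    stop("snps must be a non-empty data.frame (see snp_spec)")
  if (any(snps$raf < 0 | snps$raf > 1) || any(!is.finite(snps$raf)))
    stop("invalid raf: must lie in [0, 1]")
  if (!is.finite(ld_rho) || abs(ld_rho) > 1)
    stop("invalid ld_rho: |ld_rho| must be <= 1")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(snps)
  thr <- stats::qnorm(snps$raf)
  draw_haplotypes <- function() {
    z <- matrix(0, n_subjects, m)
    z[, 1] <- stats::rnorm(n_subjects)
    if (m > 1) {
      s <- sqrt(1 - ld_rho^2)
      for (j in 2:m)
        z[, j] <- ld_rho * z[, j - 1] + s * stats::rnorm(n_subjects)
    }
    # allele carried when latent value falls below the frequency quantile;
    # raf = 0 gives qnorm(0) = -Inf so the column is structurally zero
    matrix(as.integer(z < rep(thr, each = n_subjects)), n_subjects, m)
  }
  dosage <- draw_haplotypes() + draw_haplotypes()
  dimnames(dosage) <- list(sprintf("S%04d", seq_len(n_subjects)), snps$snp_id)
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%s:%d-%d)\n",
              nrow(x$dosage), ncol(x$dosage), x$snps$chrom[1],
              min(x$snps$pos), max(x$snps$pos)))
  af <- colMeans(x$dosage, na.rm = TRUE) / 2
  cat("effect-allele frequency range:",
      sprintf("%.4g - %.4g", min(af), max(af)), "\n")
  invisible(x)
}

#' Simulate a binary exposure with missingness
#'
#' Generates a 0/1 exposure ("low"/"high" time reading or outdoors) with a
#' given prevalence of the high category, and missing entries flagged as `NA`.
#' The defaults reproduce the study-style split of roughly 2,775 low / 1,686
#' high / 739 missing at n = 5,200.
#'
#' @param n_subjects Number of subjects.
#' @param p_high Probability of exposure level 1 among non-missing subjects.
#' @param missing_rate Probability an entry is missing.
#' @param seed Integer seed.
#' @return Integer vector in \{0, 1, NA\}.
#' @export
simulate_exposure <- function(n_subjects, p_high = 1686 / (1686 + 2775),
                              missing_rate = 739 / 5200, seed = NULL) {
  stopifnot(n_subjects >= 1)
  if (p_high < 0 || p_high > 1 || missing_rate < 0 || missing_rate > 1)
    stop("p_high and missing_rate must be probabilities")
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rbinom(n_subjects, 1L, p_high)
  x[stats::runif(n_subjects) < missing_rate] <- NA_integer_
  x
}

#' Trajectory generative parameters
#'
#' Collects the coefficients of the generative model for refractive-error
#' trajectories: a cubic polynomial in centered age, genotype / reading main
#' effects and age interactions up to the 3-way genotype x reading x age term,
#' a sex effect, a 2x2 random intercept/slope covariance and a residual
#' variance. Defaults describe a mildly myopizing cohort: slow myopic drift
#' with age, a carrier x reading x age interaction of -0.06 D/yr, and
#' between-subject variability dominating the residual.
#'
#' @param beta0,beta1,beta2,beta3 Fixed polynomial age coefficients (D, D/yr,
#'   D/yr^2, D/yr^3) at centered age.
#' @param gamma_g,gamma_ga Genotype main effect (D) and genotype x age slope
#'   (D/yr).
#' @param gamma_r,gamma_ra Reading main effect (D) and reading x age slope
#'   (D/yr).
#' @param gamma_gr,gamma_gra Genotype x reading (D) and genotype x reading x
#'   age (D/yr) interactions.
#' @param beta_sex Sex effect (D).
#' @param g00,g11,g01 Random intercept variance (D^2), slope variance
#'   (D^2/yr^2) and their covariance; \[\[g00, g01\], \[g01, g11\]\] must be
#'   positive semidefinite.
#' @param sigma2_eps Residual variance (D^2), >= 0.
#' @param age_center Centering age in years (default 11.5, midpoint of the
#'   7.5-15.5 visit window).
#' @return A list of class `trajectory_params`.
#' @export
trajectory_params <- function(beta0 = 0.3, beta1 = -0.10, beta2 = -0.008,
                              beta3 = -0.001,
                              gamma_g = -0.15, gamma_ga = -0.05,
                              gamma_r = -0.05, gamma_ra = -0.10,
                              gamma_gr = -0.05, gamma_gra = -0.06,
                              beta_sex = 0.05,
                              g00 = 1.2, g11 = 0.02, g01 = -0.05,
                              sigma2_eps = 0.15, age_center = 11.5) {
  p <- list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
            gamma_g = gamma_g, gamma_ga = gamma_ga, gamma_r = gamma_r,
            gamma_ra = gamma_ra, gamma_gr = gamma_gr, gamma_gra = gamma_gra,
            beta_sex = beta_sex, g00 = g00, g11 = g11, g01 = g01,
            sigma2_eps = sigma2_eps, age_center = age_center)
  G <- matrix(c(g00, g01, g01, g11), 2, 2)
  if (any(eigen(G, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
    stop("random-effect covariance [[g00, g01], [g01, g11]] must be positive semidefinite")
  if (sigma2_eps < 0) stop("sigma2_eps must be >= 0")
  class(p) <- "trajectory_params"
  p
}

#' Visit schedule for a longitudinal cohort
#'
#' The default targets the five research-clinic visits at approximately 7.5,
#' 10.5, 11.5, 12.5 and 15.5 years, with small Gaussian jitter on attained
#' age, and a 3/4/5 attended-visit mix matching the 833/1,696/2,671 subject
#' proportions out of 5,200.
#'
#' @param target_ages Strictly increasing visit ages in years.
#' @param jitter_sd SD (years) of Gaussian jitter on each attained age.
#' @param visit_count_probs Probabilities of attending 3, 4 or 5 visits; must
#'   sum to 1.
#' @return A list of class `visit_schedule`.
#' @export
visit_schedule <- function(target_ages = c(7.5, 10.5, 11.5, 12.5, 15.5),
                           jitter_sd = 0.15,
                           visit_count_probs = c(833, 1696, 2671) / 5200) {
  if (any(diff(target_ages) <= 0)) stop("target_ages must be strictly increasing")
  if (abs(sum(visit_count_probs) - 1) > 1e-8)
    stop("visit_count_probs must sum to 1")
  if (length(visit_count_probs) != 3)
    stop("visit_count_probs gives probabilities for 3, 4 and 5 attended visits")
  structure(list(target_ages = target_ages, jitter_sd = jitter_sd,
                 visit_count_probs = visit_count_probs),
            class = "visit_schedule")
}

#' Simulate longitudinal refractive trajectories
#'
#' Generates long-format spherical-equivalent records from the trajectory
#' model: for subject i at centered age a,
#' `y = beta0 + beta1*a + beta2*a^2 + beta3*a^3 + gamma_g*g + gamma_ga*g*a +
#'  gamma_r*r + gamma_ra*r*a + gamma_gr*g*r + gamma_gra*g*r*a + beta_sex*s +
#'  b0_i + b1_i*a + eps`, with (b0, b1) drawn from the 2x2 random-effect
#' covariance and eps from `sigma2_eps`. Each subject attends 3, 4 or 5 of the
#' scheduled visits; dropped visits are chosen uniformly at random.
#'
#' @param genotypes Numeric vector (carrier 0/1 or dosage) per subject.
#' @param exposure 0/1/NA reading exposure per subject. A missing exposure
#'   contributes 0 to the generative mean (reference level); such subjects
#'   keep their records and are excluded downstream by the model builders.
#' @param params A [trajectory_params()] object.
#' @param schedule A [visit_schedule()] object.
#' @param sex 0/1 vector per subject (default all 0).
#' @param seed Integer seed.
#' @return A list of class `long_phenotypes` with `phenotypes` (long
#'   `data.frame`: `subject_id`, `age_years`, `sph_equiv_D`) and `covariates`
#'   (`subject_id`, `sex`, `genotype`, `reading`).
#' @export
simulate_trajectories <- function(genotypes, exposure, params = trajectory_params(),
                                  schedule = visit_schedule(), sex = NULL,
                                  seed = NULL) {
  n <- length(genotypes)
  if (length(exposure) != n)
    stop("genotypes and exposure must share the subject dimension")
  if (is.null(sex)) sex <- integer(n)
  if (length(sex) != n) stop("sex must share the subject dimension")
  stopifnot(inherits(params, "trajectory_params"),
            inherits(schedule, "visit_schedule"))
  if (!is.null(seed)) set.seed(seed)
  G <- matrix(c(params$g00, params$g01, params$g01, params$g11), 2, 2)
  ev <- eigen(G, symmetric = TRUE)
  if (any(ev$values < -1e-10))
    stop("random-effect covariance must be positive semidefinite")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) # PSD-safe square root
  b <- matrix(stats::rnorm(2L * n), n, 2) %*% t(L)

  n_visits_all <- length(schedule$target_ages)
  k <- sample(c(3L, 4L, 5L), n, replace = TRUE, prob = schedule$visit_count_probs)
  k <- pmin(k, n_visits_all)  # schedules with < 5 targets: attend all
  subj_ids <- sprintf("S%04d", seq_len(n))
  r_num <- ifelse(is.na(exposure), 0, exposure) # generator treats missing as reference

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- sort(sample.int(n_visits_all, k[i]))
    age <- schedule$target_ages[keep] +
      stats::rnorm(k[i], 0, schedule$jitter_sd)
    a <- age - params$age_center
    g <- genotypes[i]; r <- r_num[i]; s <- sex[i]
    mu <- params$beta0 + params$beta1 * a + params$beta2 * a^2 +
      params$beta3 * a^3 + params$gamma_g * g + params$gamma_ga * g * a +
      params$gamma_r * r + params$gamma_ra * r * a +
      params$gamma_gr * g * r + params$gamma_gra * g * r * a +
      params$beta_sex * s + b[i, 1] + b[i, 2] * a
    y <- mu + stats::rnorm(k[i], 0, sqrt(params$sigma2_eps))
    rows[[i]] <- data.frame(subject_id = subj_ids[i], age_years = age,
                            sph_equiv_D = y, stringsAsFactors = FALSE)
  }
  phen <- do.call(rbind, rows)
  rownames(phen) <- NULL
  cov <- data.frame(subject_id = subj_ids, sex = sex, genotype = genotypes,
                    reading = exposure, stringsAsFactors = FALSE)
  structure(list(phenotypes = phen, covariates = cov,
                 params = params, seed = seed),
            class = "long_phenotypes")
}

#' @export
print.long_phenotypes <- function(x, ...) {
  nv <- table(table(x$phenotypes$subject_id))
  cat(sprintf("long_phenotypes: %d subjects, %d records\n",
              nrow(x$covariates), nrow(x$phenotypes)))
  cat("visits per subject:",
      paste(sprintf("%s x%s", names(nv), nv), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper tying the generators together: an LD block of SNPs
#' including one low-frequency risk variant, a reading exposure, an outdoors
#' exposure, sex, and longitudinal phenotypes driven by the recoded carrier
#' status of the risk SNP. Defaults emulate the study's structure: a
#' risk-allele frequency of 0.01, 30 SNPs in an AR(1) LD block, five target
#' visit ages, and the printed 3/4/5-visit mix.
#'
#' @param n_subjects Cohort size.
#' @param n_snps Number of SNPs in the block.
#' @param risk_index Index of the risk SNP within the block.
#' @param risk_raf Risk-allele frequency of the risk SNP.
#' @param other_raf_range Range from which the other SNPs' frequencies are
#'   drawn uniformly.
#' @param ld_rho Adjacent-SNP latent correlation.
#' @param region_start,region_chrom Basepair start and chromosome of the block
#'   (SNPs spaced ~2 kb apart).
#' @param params,schedule See [trajectory_params()] and [visit_schedule()].
#' @param seed Integer seed (default 17) governing every draw.
#' @return List of class `synthetic_cohort` with elements `genotypes`
#'   (`genotype_matrix`), `phenotypes`, `covariates` (adds `outdoors` and the
#'   carrier-coded `genotype`), `risk_snp` and `seed`.
#' @export
simulate_cohort <- function(n_subjects = 5200, n_snps = 30, risk_index = 15,
                            risk_raf = 0.01, other_raf_range = c(0.01, 0.30),
                            ld_rho = 0.8, region_start = 129904497L,
                            region_chrom = "11",
                            params = trajectory_params(),
                            schedule = visit_schedule(), seed = 17) {
  set.seed(seed)
  raf <- stats::runif(n_snps, other_raf_range[1], other_raf_range[2])
  raf[risk_index] <- risk_raf
  snps <- snp_spec(sprintf("snp%02d", seq_len(n_snps)), region_chrom,
                   region_start + 2000L * (seq_len(n_snps) - 1L), raf = raf)
  geno <- simulate_genotypes(n_subjects, snps, ld_rho = ld_rho)
  carrier <- recode_rare_homozygotes(geno$dosage[, risk_index])
  reading <- simulate_exposure(n_subjects)
  outdoors <- simulate_exposure(n_subjects, p_high = 2145 / (2145 + 2349),
                                missing_rate = 706 / 5200)
  sex <- stats::rbinom(n_subjects, 1L, 0.5)
  traj <- simulate_trajectories(carrier, reading, params, schedule, sex)
  cov <- traj$covariates
  cov$outdoors <- outdoors
  structure(list(genotypes = geno, phenotypes = traj$phenotypes,
                 covariates = cov, risk_snp = snps$snp_id[risk_index],
                 params = params, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort (seed %d): %d subjects, %d SNPs, risk SNP %s\n",
              x$seed, nrow(x$covariates), ncol(x$genotypes$dosage), x$risk_snp))
  invisible(x)
}
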
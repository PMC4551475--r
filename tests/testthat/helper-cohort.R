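# Shared fixture builders. Everything is generated in code under fixed seeds.

# A small LD block with one low-frequency risk SNP in the middle.
make_block_snps <- function(n_snps = 10, risk_index = ceiling(n_snps / 2),
                            risk_raf = 0.01, raf = 0.25, start = 1000L,
                            spacing = 1000L) {
  rafs <- rep(raf, n_snps)
  rafs[risk_index] <- risk_raf
  snp_spec(sprintf("rs%02d", seq_len(n_snps)), "11",
           start + spacing * (seq_len(n_snps) - 1L), raf = rafs)
}

# Null cohort for calibration: genotypes + independent N(0,1) phenotype.
make_null_cohort <- function(n = 400, n_snps = 30, ld_rho = 0.8, seed = 1) {
  set.seed(seed)
  snps <- make_block_snps(n_snps, risk_index = ceiling(n_snps / 2))
  g <- simulate_genotypes(n, snps, ld_rho = ld_rho)
  list(genotypes = g, phenotype = rnorm(n))
}

# Longitudinal data with every generative effect switched off except those
# passed in `...` (forwarded to trajectory_params).
make_traj <- function(n = 300, p_carrier = 0.5, p_reading = 0.5, seed = 1,
                      schedule = visit_schedule(), ...) {
  set.seed(seed)
  g <- rbinom(n, 1, p_carrier)
  r <- rbinom(n, 1, p_reading)
  sex <- rbinom(n, 1, 0.5)
  pars <- trajectory_params(...)
  simulate_trajectories(g, r, pars, schedule, sex = sex)
}

# Generative parameters with all effects and variances zeroed; override via ...
null_params <- function(...) {
  args <- list(beta0 = 0, beta1 = 0, beta2 = 0, beta3 = 0, gamma_g = 0,
               gamma_ga = 0, gamma_r = 0, gamma_ra = 0, gamma_gr = 0,
               gamma_gra = 0, beta_sex = 0, g00 = 0, g11 = 0, g01 = 0,
               sigma2_eps = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(trajectory_params, args)
}

# Closed-form simple-regression p-value (correlation route), independent of
# the package's QR-based OLS path. No covariates.
oracle_simple_p <- function(x, y) {
  n <- length(x)
  r <- suppressWarnings(cor(x, y))
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(abs(t), n - 2, lower.tail = FALSE)
}

# minimal recursive permutation generator, independent of the package's
# internal enumerator (oracle use only)
combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(combinat_perms(v[-i]), function(p) c(v[i], p)))
  out
}
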
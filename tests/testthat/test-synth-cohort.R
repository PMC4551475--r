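test_that("snp_spec validates frequencies and positions", {
  expect_error(snp_spec("rs1", "11", 100, raf = 1.2), "raf")
  expect_error(snp_spec(c("a", "b"), "11", c(200, 100), raf = c(0.1, 0.1)),
               "increasing")
})

test_that("dosages stay in [0,2], impossible alleles give empty columns", {
  snps <- snp_spec(c("rs1", "rs2", "rs3"), "11", c(1, 2, 3) * 1000,
                   raf = c(0, 0.3, 1))
  g <- simulate_genotypes(400, snps, seed = 7)
  expect_true(all(g$dosage %in% 0:2))
  expect_true(all(g$dosage[, "rs1"] == 0))
  expect_true(all(g$dosage[, "rs3"] == 2))
  expect_error(simulate_genotypes(10, snps, ld_rho = 1.5), "ld_rho")
})

test_that("carrier fraction matches the Hardy-Weinberg closed form at RAF 0.01", {
  g <- simulate_genotypes(1e5, snp_spec("rs1", "11", 1000, raf = 0.01),
                          seed = 11)
  carrier <- mean(g$dosage >= 1)
  expected <- 1 - 0.99^2
  tol <- 3 * sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(carrier - expected), tol)
})

test_that("empirical allele frequency converges to raf", {
  snps <- make_block_snps(5, raf = 0.2)
  g <- simulate_genotypes(5e4, snps, ld_rho = 0.5, seed = 3)
  af <- colMeans(g$dosage) / 2
  tol <- 3 * sqrt(snps$raf * (1 - snps$raf) / (2 * 5e4))
  expect_true(all(abs(af - snps$raf) < tol))
})

test_that("LD structure matches an independently coded copula oracle", {
  # oracle: direct bivariate-normal haplotype simulation via Cholesky,
  # written without the package's AR recursion
  oracle_dosage_cor <- function(n, rho, raf, seed) {
    set.seed(seed)
    Lc <- chol(matrix(c(1, rho, rho, 1), 2))
    hap <- function() {
      z <- matrix(rnorm(2 * n), n, 2) %*% Lc
      matrix(as.integer(z < qnorm(raf)), n, 2)
    }
    d <- hap() + hap()
    cor(d[, 1], d[, 2])
  }
  n <- 5e4
  r_oracle <- oracle_dosage_cor(n, 0.9, 0.3, seed = 21)
  g <- simulate_genotypes(n, snp_spec(c("a", "b"), "11", c(1000, 2000),
                                      raf = c(0.3, 0.3)),
                          ld_rho = 0.9, seed = 22)
  r_pkg <- cor(g$dosage[, 1], g$dosage[, 2])
  expect_lt(abs(r_pkg - r_oracle), 0.02)
})

test_that("genotype simulation is bit-identical for a fixed seed", {
  snps <- make_block_snps(6)
  g1 <- simulate_genotypes(200, snps, ld_rho = 0.7, seed = 5)
  g2 <- simulate_genotypes(200, snps, ld_rho = 0.7, seed = 5)
  expect_identical(g1$dosage, g2$dosage)
})

test_that("exposure frequencies and missingness match their targets", {
  expect_true(all(simulate_exposure(500, p_high = 0, missing_rate = 0,
                                    seed = 1) == 0))
  # default split emulates 2,775 low / 1,686 high / 739 missing at n = 5,200
  x <- simulate_exposure(5200, seed = 2)
  p_miss <- 739 / 5200
  expect_lt(abs(mean(is.na(x)) - p_miss),
            3 * sqrt(p_miss * (1 - p_miss) / 5200))
  p_high <- 1686 / (1686 + 2775)
  obs_high <- mean(x[!is.na(x)])
  expect_lt(abs(obs_high - p_high),
            3 * sqrt(p_high * (1 - p_high) / sum(!is.na(x))))
  y <- simulate_exposure(1e4, p_high = 0.5, missing_rate = 0, seed = 3)
  expect_lt(abs(mean(y) - 0.5), 3 * sqrt(0.25 / 1e4))
})

test_that("trajectory generator reproduces the deterministic mean structure", {
  sched <- visit_schedule(target_ages = c(7.5, 11.5, 15.5), jitter_sd = 0,
                          visit_count_probs = c(1, 0, 0))
  # all coefficients zero except the intercept: every record is 0.3
  t1 <- simulate_trajectories(c(0, 1), c(0, 1), null_params(beta0 = 0.3),
                              sched, seed = 1)
  expect_true(all(t1$phenotypes$sph_equiv_D == 0.3))
  # only the 3-way term: difference between centered ages +4 and -4 is -0.4
  t2 <- simulate_trajectories(1, 1, null_params(gamma_gra = -0.05),
                              sched, seed = 1)
  y <- t2$phenotypes
  expect_equal(y$sph_equiv_D[y$age_years == 15.5] -
                 y$sph_equiv_D[y$age_years == 7.5], -0.4)
})

test_that("random-intercept variance is recovered by a brute-force refit oracle", {
  sched <- visit_schedule(jitter_sd = 0)
  tr <- make_traj(2000, seed = 31, schedule = sched, g00 = 1.5,
                  g11 = 0, g01 = 0, sigma2_eps = 0.1,
                  beta1 = 0, beta2 = 0, beta3 = 0, gamma_g = 0, gamma_ga = 0,
                  gamma_r = 0, gamma_ra = 0, gamma_gr = 0, gamma_gra = 0,
                  beta_sex = 0)
  # per-subject OLS intercepts at centered age 0
  ints <- vapply(split(tr$phenotypes, tr$phenotypes$subject_id), function(d)
    unname(coef(lm(sph_equiv_D ~ I(age_years - 11.5), data = d))[1]),
    numeric(1))
  expect_lt(abs(var(ints) - 1.5) / 1.5, 0.10)
})

test_that("marginal variance at the centering age equals g00 + sigma2_eps", {
  sched <- visit_schedule(target_ages = c(7.5, 11.5, 15.5), jitter_sd = 0,
                          visit_count_probs = c(1, 0, 0))
  tr <- make_traj(4000, seed = 41, schedule = sched, g00 = 0.9,
                  sigma2_eps = 0.2, g11 = 0.02)
  y0 <- tr$phenotypes$sph_equiv_D[tr$phenotypes$age_years == 11.5]
  expect_lt(abs(var(y0) - 1.1) / 1.1, 0.05)
})

test_that("attended visit counts lie in {3,4,5} and follow the study mix", {
  tr <- make_traj(5200, seed = 51)
  nv <- table(tr$phenotypes$subject_id)
  expect_true(all(nv %in% 3:5))
  obs <- as.numeric(table(factor(nv, levels = 3:5))) / 5200
  target <- c(833, 1696, 2671) / 5200
  tol <- 3 * sqrt(target * (1 - target) / 5200)
  expect_true(all(abs(obs - target) < tol))
})

test_that("non-PSD random-effect covariance is rejected", {
  expect_error(trajectory_params(g00 = 0.1, g11 = 0.1, g01 = 0.5), "semidefinite")
  expect_error(trajectory_params(sigma2_eps = -1), "sigma2_eps")
})

test_that("simulate_cohort is reproducible and carries the risk SNP", {
  c1 <- simulate_cohort(n_subjects = 300, seed = 17)
  c2 <- simulate_cohort(n_subjects = 300, seed = 17)
  expect_identical(c1$phenotypes, c2$phenotypes)
  expect_identical(c1$genotypes$dosage, c2$genotypes$dosage)
  expect_equal(c1$risk_snp, "snp15")
  expect_true(all(c1$covariates$genotype %in% c(0, 1)))
})
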
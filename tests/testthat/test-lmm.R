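test_that("rare homozygotes are recoded to carriers, idempotently", {
  expect_equal(recode_rare_homozygotes(c(0, 1, 2, 1)), c(0L, 1L, 1L, 1L))
  expect_equal(recode_rare_homozygotes(c(0, 0, 0)), c(0L, 0L, 0L))
  expect_equal(recode_rare_homozygotes(c(2, NA, 1)), c(1L, NA, 1L))
  once <- recode_rare_homozygotes(c(0, 1, 2))
  expect_identical(recode_rare_homozygotes(once), once)
  expect_error(recode_rare_homozygotes(c(0.7, 1)), "hard-call")
})

test_that("build_design orders columns per spec and logs exclusions", {
  tr <- make_traj(60, seed = 1, g00 = 0.5, sigma2_eps = 0.1)
  tr$covariates$reading[1:7] <- NA
  spec <- lmm_spec(c("intercept", "age", "genotype", "reading",
                     "genotype:reading:age"))
  d <- build_design(tr, tr$covariates, spec)
  expect_identical(colnames(d$X), spec$fixed_terms)
  expect_equal(d$log$n_excluded_missing_covariate, 7)
  expect_equal(d$log$n_subjects_analyzed, 53)
  # spec term without its column
  cv2 <- tr$covariates[, c("subject_id", "sex", "genotype")]
  expect_error(build_design(tr, cv2, spec), "reading")
  # model without reading terms keeps everyone
  d2 <- build_design(tr, cv2, lmm_spec(c("intercept", "age", "genotype")))
  expect_equal(d2$log$n_subjects_analyzed, 60)
})

test_that("zero variance components collapse the LMM to the OLS oracle", {
  set.seed(2)
  g <- rbinom(150, 1, 0.5)
  tr <- simulate_trajectories(g, rbinom(150, 1, 0.5),
                              null_params(sigma2_eps = 0.2, beta0 = 0.3,
                                          beta1 = -0.1, gamma_g = -0.4),
                              visit_schedule(), seed = 2)
  spec <- lmm_spec(c("intercept", "age", "genotype"))
  d <- build_design(tr, tr$covariates, spec)
  fit <- fit_lmm(d, estimation = "ML")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$G_hat)), 1e-3)
  b_ols <- solve(crossprod(d$X), crossprod(d$X, d$y))  # normal equations
  expect_equal(unname(fit$beta_hat), unname(drop(b_ols)), tolerance = 1e-4)
})

test_that("balanced random-intercept data matches the ANOVA moment estimator", {
  sched <- visit_schedule(jitter_sd = 0, visit_count_probs = c(0, 0, 1))
  set.seed(3)
  tr <- simulate_trajectories(rbinom(500, 1, 0.5), rbinom(500, 1, 0.5),
                              null_params(g00 = 0.8, sigma2_eps = 0.25),
                              sched, seed = 3)
  d <- build_design(tr, tr$covariates, lmm_spec(c("intercept")))
  fit <- fit_lmm(d, estimation = "REML")
  # one-way ANOVA method of moments: sigma_b^2 = (MSB - MSW)/k
  y <- d$y; subj <- d$subject
  k <- 5
  means <- tapply(y, subj, mean)
  msb <- k * var(means)
  msw <- sum(tapply(y, subj, function(v) sum((v - mean(v))^2))) /
    (length(y) - nlevels(subj))
  g00_mom <- (msb - msw) / k
  expect_lt(abs(fit$G_hat[1, 1] - g00_mom) / g00_mom, 0.05)
})

test_that("the fit agrees with an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  tr <- make_traj(250, seed = 4)
  fit <- trajectory_lmm(tr$phenotypes, tr$covariates, model = "full",
                        estimation = "REML", min_visits = 1)
  d <- tr$phenotypes
  cv <- tr$covariates
  ix <- match(d$subject_id, cv$subject_id)
  d$g <- cv$genotype[ix]; d$r <- cv$reading[ix]
  d <- d[complete.cases(d), ]
  d$a <- d$age_years - 11.5
  m <- nlme::lme(sph_equiv_D ~ a + I(a^2) + I(a^3) + g + g:a + r + r:a +
                   g:r + g:r:a,
                 random = ~ a | subject_id, data = d, method = "REML",
                 control = nlme::lmeControl(opt = "optim"))
  expect_equal(fit$loglik, as.numeric(logLik(m)), tolerance = 1e-5)
  fe <- nlme::fixef(m)
  key <- names(fe)[vapply(strsplit(names(fe), ":"), function(s)
    setequal(s, c("g", "r", "a")), logical(1))]
  expect_equal(unname(coef(fit)[["genotype:reading:age"]]),
               unname(fe[[key]]), tolerance = 1e-4)
  se_mine <- sqrt(vcov(fit)["genotype:reading:age", "genotype:reading:age"])
  se_ref <- sqrt(diag(vcov(m))[[key]])
  expect_lt(abs(se_mine - se_ref) / se_ref, 0.10)
})

test_that("the optimum dominates the generative parameters in likelihood", {
  tr <- make_traj(200, seed = 5)
  d <- build_design(tr, tr$covariates, lmm_spec(estimation = "ML"))
  fit <- fit_lmm(d, estimation = "ML")
  pre <- myodev:::.lmm_precompute(d$y, d$X, d$Z, d$subject)
  # generative values: G = diag-ish from trajectory_params defaults
  pars <- tr$params
  s2 <- pars$sigma2_eps
  Lam <- t(chol(matrix(c(pars$g00, pars$g01, pars$g01, pars$g11), 2) / s2))
  th <- c(log(Lam[1, 1]), Lam[2, 1], log(Lam[2, 2]))
  obj_true <- myodev:::.lmm_objective(th, pre, ncol(d$X), length(d$y),
                                      reml = FALSE)
  expect_gte(fit$loglik, -0.5 * obj_true - 1e-6)
})

test_that("fit is invariant to subject and row reordering", {
  tr <- make_traj(80, seed = 6)
  spec <- lmm_spec(c("intercept", "age", "genotype", "genotype:age"))
  d1 <- build_design(tr, tr$covariates, spec)
  perm <- sample(nrow(tr$phenotypes))
  tr2 <- tr
  tr2$phenotypes <- tr$phenotypes[perm, ]
  cvperm <- sample(nrow(tr$covariates))
  tr2$covariates <- tr$covariates[cvperm, ]
  d2 <- build_design(tr2, tr2$covariates, spec)
  f1 <- fit_lmm(d1); f2 <- fit_lmm(d2)
  expect_equal(f1$beta_hat, f2$beta_hat, tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("REML and ML variance estimates approach each other with n", {
  gap <- vapply(c(100, 600), function(n) {
    tr <- make_traj(n, seed = 7)
    d <- build_design(tr, tr$covariates,
                      lmm_spec(c("intercept", "age", "genotype")))
    abs(fit_lmm(d, "REML")$G_hat[1, 1] - fit_lmm(d, "ML")$G_hat[1, 1])
  }, numeric(1))
  expect_lt(gap[2], gap[1])
})

test_that("wald_test applies the normal reference two-sidedly", {
  fake <- structure(list(beta_hat = c(a = 0, b = 1.96), terms = c("a", "b"),
                         beta_cov = matrix(diag(2), 2, 2,
                                           dimnames = list(c("a", "b"),
                                                           c("a", "b")))),
                    class = "traj_lmm")
  wa <- wald_test(fake, "a")
  expect_equal(wa$p, 1)
  wb <- wald_test(fake, "b")
  expect_equal(wb$p, 0.05, tolerance = 1e-3)
  expect_error(wald_test(fake, "zzz"), "available")
})

test_that("lrt contracts: identical fits, nestedness, REML refusal", {
  tr <- make_traj(100, seed = 8)
  spec_full <- lmm_spec(c("intercept", "age", "genotype"), estimation = "ML")
  d <- build_design(tr, tr$covariates, spec_full)
  f <- fit_lmm(d, "ML")
  self <- lrt(f, f)
  expect_equal(self$chi2, 0)
  expect_equal(self$p, 1)
  fr <- fit_lmm(d, "REML")
  expect_error(lrt(fr, fr), "REML")
})

test_that("stratified fits swap exactly under label exchange and refuse tiny strata", {
  tr <- make_traj(120, seed = 9, gamma_ga = -0.1)
  s1 <- stratified_trajectory(tr$phenotypes, tr$covariates)
  cv2 <- tr$covariates
  cv2$reading <- 1 - cv2$reading
  s2 <- stratified_trajectory(tr$phenotypes, cv2)
  expect_equal(s1$low$beta_hat, s2$high$beta_hat, tolerance = 1e-8)
  expect_equal(s1$high$beta_hat, s2$low$beta_hat, tolerance = 1e-8)
  cv3 <- tr$covariates
  cv3$reading <- c(rep(1, 5), rep(0, nrow(cv3) - 5))
  expect_error(stratified_trajectory(tr$phenotypes, cv3), "fewer than 10")
  cv4 <- tr$covariates
  cv4$reading <- 1
  expect_error(stratified_trajectory(tr$phenotypes, cv4), "binary")
})

test_that("a stratum-specific genotype-age effect is detected where it exists", {
  hits <- 0L
  for (rep in 1:40) {
    set.seed(4000 + rep)
    n <- 800
    g <- rbinom(2 * n, 1, 0.3)
    r <- rep(c(0L, 1L), each = n)
    pars_lo <- null_params(g00 = 1.0, g11 = 0.015, sigma2_eps = 0.15)
    pars_hi <- null_params(g00 = 1.0, g11 = 0.015, sigma2_eps = 0.15,
                           gamma_ga = -0.06)
    lo <- simulate_trajectories(g[1:n], r[1:n], pars_lo)
    hi <- simulate_trajectories(g[(n + 1):(2 * n)], r[(n + 1):(2 * n)],
                                pars_hi)
    hi$phenotypes$subject_id <- paste0("H", hi$phenotypes$subject_id)
    hi$covariates$subject_id <- paste0("H", hi$covariates$subject_id)
    ph <- rbind(lo$phenotypes, hi$phenotypes)
    cv <- rbind(lo$covariates, hi$covariates)
    s <- stratified_trajectory(ph, cv)
    w_lo <- wald_test(s$low, "genotype:age")
    w_hi <- wald_test(s$high, "genotype:age")
    hits <- hits + (w_hi$p < 0.05 && abs(w_lo$estimate) < 0.04)
  }
  expect_gte(hits, 36)
})

test_that("predict, residuals and simulate methods are coherent", {
  tr <- make_traj(150, seed = 10)
  spec <- lmm_spec(c("intercept", "age", "genotype", "genotype:age"))
  d <- build_design(tr, tr$covariates, spec)
  fit <- fit_lmm(d)
  nd <- data.frame(age_years = c(7.5, 15.5), genotype = c(1, 1))
  pr <- predict(fit, nd)
  b <- coef(fit)
  expect_equal(pr[2] - pr[1],
               8 * b[["age"]] + 8 * b[["genotype:age"]], tolerance = 1e-10)
  res <- residuals(fit, d)
  expect_equal(length(res), fit$n_obs)
  expect_lt(abs(mean(res)), 0.2)
  sims <- simulate(fit, nsim = 2, seed = 11, n_subjects = 50)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "long_phenotypes")
})
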
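#' Recode rare homozygotes to carrier status
#'
#' For a very low-frequency risk allele, homozygous carriers are too rare to
#' estimate a separate effect; hard-called genotypes coded 0/1/2 are recoded
#' to carrier status by mapping 2 to 1. Missing values are preserved and the
#' operation is idempotent.
#'
#' @param genotype Vector with values in \{0, 1, 2\} or `NA`.
#' @return Integer carrier vector in \{0, 1, NA\}.
#' @examples
#' recode_rare_homozygotes(c(0, 1, 2, 1, NA))
#' @export
recode_rare_homozygotes <- function(genotype) {
  g <- genotype[!is.na(genotype)]
  if (any(g != round(g)) || any(!g %in% c(0, 1, 2)))
    stop("genotype must be hard-called 0/1/2; hard-call dosages first")
  out <- as.integer(genotype)
  out[!is.na(out) & out == 2L] <- 1L
  out
}

# Term definitions for the trajectory model ---------------------------------

.lmm_all_terms <- c("intercept", "age", "age2", "age3", "sex", "genotype",
                    "genotype:age", "reading", "reading:age",
                    "genotype:reading", "genotype:reading:age")

#' Specify a trajectory mixed model
#'
#' Fixed-effect terms are drawn from the trajectory vocabulary: a cubic
#' polynomial in centered age, sex, genotype (carrier-coded), reading, and
#' their age interactions up to genotype x reading x age. Random effects are
#' fixed to a per-subject intercept and linear age slope.
#'
#' @param fixed_terms Ordered subset of
#'   `c("intercept", "age", "age2", "age3", "sex", "genotype",
#'   "genotype:age", "reading", "reading:age", "genotype:reading",
#'   "genotype:reading:age")`. The intercept is always included.
#' @param estimation `"REML"` (default, for reporting) or `"ML"` (for
#'   likelihood-ratio comparison of fixed-effect structures).
#' @param age_center Centering age in years.
#' @return A list of class `lmm_spec`.
#' @export
lmm_spec <- function(fixed_terms = .lmm_all_terms,
                     estimation = c("REML", "ML"), age_center = 11.5) {
  estimation <- match.arg(estimation)
  bad <- setdiff(fixed_terms, .lmm_all_terms)
  if (length(bad))
    stop("unknown fixed term(s): ", paste(bad, collapse = ", "),
         "; valid terms are: ", paste(.lmm_all_terms, collapse = ", "))
  if (!"intercept" %in% fixed_terms)
    fixed_terms <- c("intercept", fixed_terms)
  structure(list(fixed_terms = fixed_terms, estimation = estimation,
                 age_center = age_center), class = "lmm_spec")
}

#' Build per-subject design blocks for the trajectory model
#'
#' Joins long-format phenotypes with subject-level covariates, centers age,
#' builds the fixed-effect matrix in the spec's term order and the
#' random-effect matrix \[1, centered age\], and excludes listwise any subject
#' missing a covariate required by the spec. Exclusion counts are logged in
#' the returned `log` element (mirroring analysis-set bookkeeping such as a
#' 5,200 to 4,461 reduction when a reading term enters the model).
#'
#' @param long_data `data.frame` with `subject_id`, `age_years`,
#'   `sph_equiv_D` (or a `long_phenotypes` object).
#' @param covariates `data.frame` with `subject_id` plus whichever of `sex`,
#'   `genotype`, `reading` the spec needs.
#' @param spec An [lmm_spec()].
#' @param min_visits Minimum records per subject (default 1).
#' @return List with `y`, `X`, `Z`, `subject` (factor), `spec`, `log`.
#' @export
build_design <- function(long_data, covariates, spec = lmm_spec(),
                         min_visits = 1) {
  if (inherits(long_data, "long_phenotypes")) long_data <- long_data$phenotypes
  stopifnot(inherits(spec, "lmm_spec"))
  need <- c("subject_id", "age_years", "sph_equiv_D")
  if (!all(need %in% names(long_data)))
    stop("long_data must have columns ", paste(need, collapse = ", "))
  vars <- unique(unlist(strsplit(setdiff(spec$fixed_terms,
                                         c("intercept", "age", "age2", "age3")), ":")))
  vars <- setdiff(vars, "age")
  miss_col <- setdiff(vars, names(covariates))
  if (length(miss_col))
    stop("spec requires covariate column(s) missing from `covariates`: ",
         paste(miss_col, collapse = ", "))
  if (!all(long_data$subject_id %in% covariates$subject_id))
    stop("phenotype rows reference subjects absent from covariates")

  log <- list(n_subjects_input = length(unique(long_data$subject_id)))
  # listwise exclusion on required covariates
  cc <- covariates[stats::complete.cases(covariates[, c("subject_id", vars),
                                                    drop = FALSE]), ]
  log$n_excluded_missing_covariate <- log$n_subjects_input -
    sum(unique(long_data$subject_id) %in% cc$subject_id)
  d <- long_data[stats::complete.cases(long_data) &
                   long_data$subject_id %in% cc$subject_id, ]
  nv <- table(d$subject_id)
  keep_subj <- names(nv)[nv >= min_visits]
  log$n_excluded_few_visits <- sum(nv < min_visits)
  d <- d[d$subject_id %in% keep_subj, ]
  if (nrow(d) == 0) stop("no records remain after exclusions")
  idx <- match(d$subject_id, cc$subject_id)
  a <- d$age_years - spec$age_center

  colbuild <- list(
    intercept = function() rep(1, nrow(d)),
    age = function() a, age2 = function() a^2, age3 = function() a^3,
    sex = function() cc$sex[idx],
    genotype = function() cc$genotype[idx],
    `genotype:age` = function() cc$genotype[idx] * a,
    reading = function() cc$reading[idx],
    `reading:age` = function() cc$reading[idx] * a,
    `genotype:reading` = function() cc$genotype[idx] * cc$reading[idx],
    `genotype:reading:age` = function() cc$genotype[idx] * cc$reading[idx] * a
  )
  X <- vapply(spec$fixed_terms, function(t) as.numeric(colbuild[[t]]()),
              numeric(nrow(d)))
  colnames(X) <- spec$fixed_terms
  Z <- cbind(intercept = rep(1, nrow(d)), age = a)
  subject <- factor(d$subject_id, levels = unique(d$subject_id))
  log$n_subjects_analyzed <- nlevels(subject)
  log$n_obs <- nrow(d)
  list(y = d$sph_equiv_D, X = X, Z = Z, subject = subject,
       spec = spec, log = log)
}

# Profiled likelihood machinery ----------------------------------------------
#
# The marginal covariance per subject is V_i = sigma^2 (I + Z_i Psi Z_i')
# with Psi the relative random-effect covariance, parameterized by the
# log-Cholesky vector theta: Lambda = [exp(t1) 0; t2 exp(t3)],
# Psi = Lambda Lambda'. Both beta (by GLS) and sigma^2 are profiled out
# analytically, so the optimizer works on three unconstrained parameters.
# All per-subject cross-products are precomputed once; each objective
# evaluation is O(n_subjects) in 2x2 algebra.

.lmm_precompute <- function(y, X, Z, subject) {
  sp <- split(seq_along(y), subject)
  ns <- length(sp)
  p <- ncol(X)
  s11 <- s12 <- s22 <- z1 <- z2 <- numeric(ns)
  R1 <- matrix(0, ns, p); R2 <- matrix(0, ns, p)
  for (i in seq_len(ns)) {
    ix <- sp[[i]]
    Zi <- Z[ix, , drop = FALSE]
    s11[i] <- sum(Zi[, 1]^2); s12[i] <- sum(Zi[, 1] * Zi[, 2])
    s22[i] <- sum(Zi[, 2]^2)
    ZtX <- crossprod(Zi, X[ix, , drop = FALSE])
    R1[i, ] <- ZtX[1, ]; R2[i, ] <- ZtX[2, ]
    Zty <- crossprod(Zi, y[ix])
    z1[i] <- Zty[1]; z2[i] <- Zty[2]
  }
  list(s11 = s11, s12 = s12, s22 = s22, R1 = R1, R2 = R2, z1 = z1, z2 = z2,
       XtX = crossprod(X), Xty = drop(crossprod(X, y)), yty = sum(y^2),
       n_subjects = ns)
}

.lmm_lambda <- function(theta) {
  matrix(c(exp(theta[1]), theta[2], 0, exp(theta[3])), 2, 2)
}

# Returns the profiled -2 log-likelihood and, if `full`, the GLS solution.
# The 2x2 Woodbury algebra (M_i = I + L' Z_i'Z_i L per subject) is carried
# out in closed form, vectorized across subjects.
.lmm_objective <- function(theta, pre, p, N, reml, full = FALSE) {
  a <- exp(theta[1]); b <- theta[2]; cc <- exp(theta[3])
  A11 <- a^2 * pre$s11 + 2 * a * b * pre$s12 + b^2 * pre$s22
  A12 <- cc * (a * pre$s12 + b * pre$s22)
  A22 <- cc^2 * pre$s22
  det <- (1 + A11) * (1 + A22) - A12^2
  if (any(det <= 0)) return(if (full) NULL else 1e10)
  logdet <- sum(log(det))
  m11 <- (1 + A22) / det; m12 <- -A12 / det; m22 <- (1 + A11) / det
  U1 <- a * pre$R1 + b * pre$R2; U2 <- cc * pre$R2    # rows of L'Z'X
  v1 <- a * pre$z1 + b * pre$z2; v2 <- cc * pre$z2
  Sxx <- pre$XtX - (crossprod(U1, m11 * U1) + crossprod(U1, m12 * U2) +
                      crossprod(U2, m12 * U1) + crossprod(U2, m22 * U2))
  Sxy <- pre$Xty - drop(crossprod(U1, m11 * v1 + m12 * v2) +
                          crossprod(U2, m12 * v1 + m22 * v2))
  Syy <- pre$yty - sum(m11 * v1^2 + 2 * m12 * v1 * v2 + m22 * v2^2)
  cS <- tryCatch(chol(Sxx), error = function(e) NULL)
  if (is.null(cS)) return(if (full) NULL else 1e10)
  beta <- backsolve(cS, forwardsolve(t(cS), Sxy))
  rss <- max(Syy - sum(beta * Sxy), 1e-12)
  if (reml) {
    df <- N - p
    obj <- logdet + 2 * sum(log(diag(cS))) + df * (1 + log(2 * pi * rss / df))
    sigma2 <- rss / df
  } else {
    obj <- logdet + N * (1 + log(2 * pi * rss / N))
    sigma2 <- rss / N
  }
  if (!full) return(obj)
  list(objective = obj, beta = beta, sigma2 = sigma2,
       beta_cov = sigma2 * chol2inv(cS), Lambda = .lmm_lambda(theta))
}

#' Fit the refractive-trajectory linear mixed model
#'
#' Maximizes the Gaussian (restricted) likelihood of the longitudinal model
#' with per-subject marginal covariance `Z_i G Z_i' + sigma^2 I` (random
#' intercept and age slope). The relative random-effect covariance is
#' parameterized by its log-Cholesky factor, with the fixed effects profiled
#' out by generalized least squares and the residual variance profiled
#' analytically, leaving a three-parameter unconstrained optimization
#' (quasi-Newton, with a derivative-free restart if it fails). Convergence is
#' reported honestly; a fit at the variance boundary returns G projected to
#' the positive-semidefinite cone by construction.
#'
#' @param design Design blocks from [build_design()], or a list with `y`,
#'   `X`, `Z`, `subject`.
#' @param estimation `"REML"` or `"ML"`; defaults to the spec's choice.
#' @param tol Relative objective tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 500).
#' @return A `traj_lmm` object: `beta_hat` (named), `beta_cov`, `G_hat`
#'   (2x2), `sigma2_hat`, `loglik`, `estimation`, `n_subjects`, `n_obs`,
#'   `converged`, `iterations`, `theta`, `log`.
#' @export
fit_lmm <- function(design, estimation = NULL, tol = 1e-8, max_iter = 500) {
  y <- design$y; X <- design$X; Z <- design$Z; subject <- design$subject
  if (is.null(estimation))
    estimation <- if (!is.null(design$spec)) design$spec$estimation else "REML"
  estimation <- match.arg(estimation, c("REML", "ML"))
  if (nlevels(factor(subject)) < 2) stop("need at least 2 subjects")
  if (max(table(subject)) < 2)
    stop("need at least one subject with >= 2 visits")
  p <- ncol(X); N <- length(y)
  pre <- .lmm_precompute(y, X, Z, subject)
  reml <- estimation == "REML"
  fn <- function(th) .lmm_objective(th, pre, p, N, reml)

  # moment-flavored start: OLS residual variance split between the random
  # intercept and the residual, small slope variance
  ols <- stats::lm.fit(X, y)
  v <- stats::var(ols$residuals)
  starts <- list(c(log(sqrt(0.5)), 0, log(0.1)),
                 c(log(sqrt(pmax(v, 0.05))), 0, log(0.05)),
                 c(-2, 0, -2))
  best <- NULL
  iterations <- 0L
  converged <- FALSE
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(st, fn, method = "BFGS",
                   control = list(maxit = max_iter, reltol = tol)),
      error = function(e) NULL)
    if (is.null(opt))
      opt <- stats::optim(st, fn, method = "Nelder-Mead",
                          control = list(maxit = max_iter, reltol = tol))
    iterations <- iterations + sum(opt$counts, na.rm = TRUE)
    if (is.null(best) || opt$value < best$value - 1e-9) {
      best <- opt
      converged <- opt$convergence == 0
    }
    if (converged) break
  }
  # polish with Nelder-Mead from the best point (cheap; guards BFGS stalls
  # near the variance boundary)
  pol <- stats::optim(best$par, fn, method = "Nelder-Mead",
                      control = list(maxit = max_iter, reltol = tol))
  if (pol$value < best$value) {
    best <- pol
    converged <- converged || pol$convergence == 0
  }
  # boundary candidate: no random effects at all (theta -> -Inf limit); on
  # degenerate data the smooth optimizer can stall a hair above the boundary
  bnd <- c(-20, 0, -20)
  if (fn(bnd) <= best$value + 1e-8) {
    best <- list(par = bnd, value = fn(bnd))
    converged <- TRUE
  }
  sol <- .lmm_objective(best$par, pre, p, N, reml, full = TRUE)
  if (is.null(sol)) stop("singular fixed-effect GLS system at the optimum")
  G_hat <- sol$sigma2 * tcrossprod(sol$Lambda)
  beta_hat <- drop(sol$beta)
  names(beta_hat) <- colnames(X)
  dimnames(sol$beta_cov) <- list(colnames(X), colnames(X))
  structure(list(beta_hat = beta_hat, beta_cov = sol$beta_cov,
                 G_hat = G_hat, sigma2_hat = sol$sigma2,
                 loglik = -0.5 * sol$objective, estimation = estimation,
                 n_subjects = pre$n_subjects, n_obs = N,
                 converged = converged, iterations = iterations,
                 theta = best$par, spec = design$spec,
                 log = design$log, terms = colnames(X)),
            class = "traj_lmm")
}

#' Fit a refractive trajectory model from long data
#'
#' High-level interface: builds the design for one of the standard model
#' structures and fits it. `"full"` includes genotype, reading and all age
#' interactions up to the 3-way genotype x reading x age term; `"no_reading"`
#' drops every reading term; `"no_snp"` drops every genotype term. Sex can be
#' dropped (it is commonly not associated with refraction in these models).
#'
#' @param long_data Long phenotypes (see [build_design()]).
#' @param covariates Subject covariate table.
#' @param model `"full"`, `"no_reading"` or `"no_snp"`.
#' @param estimation `"REML"` or `"ML"`.
#' @param include_sex Include the sex term (default `FALSE`).
#' @param age_center Centering age.
#' @param min_visits Minimum visits per subject (default 3, the analysis-set
#'   convention for trajectory modelling).
#' @return A `traj_lmm` fit.
#' @export
trajectory_lmm <- function(long_data, covariates,
                           model = c("full", "no_reading", "no_snp"),
                           estimation = c("REML", "ML"), include_sex = FALSE,
                           age_center = 11.5, min_visits = 3) {
  model <- match.arg(model)
  estimation <- match.arg(estimation)
  terms <- switch(model,
    full = .lmm_all_terms,
    no_reading = setdiff(.lmm_all_terms, c("reading", "reading:age",
                                           "genotype:reading",
                                           "genotype:reading:age")),
    no_snp = setdiff(.lmm_all_terms, c("genotype", "genotype:age",
                                       "genotype:reading",
                                       "genotype:reading:age")))
  if (!include_sex) terms <- setdiff(terms, "sex")
  spec <- lmm_spec(terms, estimation = estimation, age_center = age_center)
  fit_lmm(build_design(long_data, covariates, spec, min_visits = min_visits))
}

#' Wald test for one fixed-effect term
#'
#' @param fit A `traj_lmm` fit.
#' @param term Term name as in `fit$terms`.
#' @return List with `estimate`, `se`, `z`, `p` (two-sided, standard-normal
#'   reference).
#' @export
wald_test <- function(fit, term) {
  stopifnot(inherits(fit, "traj_lmm"))
  if (!term %in% fit$terms)
    stop("term '", term, "' not in fit; available: ",
         paste(fit$terms, collapse = ", "))
  est <- fit$beta_hat[[term]]
  se <- sqrt(fit$beta_cov[term, term])
  z <- est / se
  list(estimate = est, se = se, z = z,
       p = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
}

#' Likelihood-ratio test between nested trajectory fits
#'
#' Both fits must be ML: REML log-likelihoods are not comparable across
#' fixed-effect structures and are refused.
#'
#' @param full,reduced Nested `traj_lmm` fits (ML).
#' @return List with `chi2`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "traj_lmm"), inherits(reduced, "traj_lmm"))
  if (full$estimation != "ML" || reduced$estimation != "ML")
    stop("LRT requires ML fits; REML log-likelihoods are not comparable ",
         "across fixed-effect structures")
  if (!all(reduced$terms %in% full$terms))
    stop("reduced model terms must be a subset of the full model's")
  chi2 <- max(2 * (full$loglik - reduced$loglik), 0)
  df <- length(full$terms) - length(reduced$terms)
  list(chi2 = chi2, df = df,
       p = if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Stratified trajectory fits by a binary exposure
#'
#' Fits the genotype trajectory model (no exposure terms) independently in
#' the low and high strata of a binary exposure, so the genotype x age slope
#' can be compared between strata.
#'
#' @param long_data,covariates As in [build_design()].
#' @param stratum_var Name of the binary stratifying column in `covariates`
#'   (default `"reading"`).
#' @param estimation,include_sex,age_center,min_visits Passed through.
#' @return List of class `stratified_lmm` with elements `low` and `high`
#'   (`traj_lmm` fits).
#' @export
stratified_trajectory <- function(long_data, covariates,
                                  stratum_var = "reading",
                                  estimation = c("REML", "ML"),
                                  include_sex = FALSE, age_center = 11.5,
                                  min_visits = 1) {
  estimation <- match.arg(estimation)
  if (inherits(long_data, "long_phenotypes")) long_data <- long_data$phenotypes
  if (!stratum_var %in% names(covariates))
    stop("stratum variable '", stratum_var, "' not in covariates")
  s <- covariates[[stratum_var]]
  lev <- sort(unique(s[!is.na(s)]))
  if (length(lev) != 2)
    stop("stratum variable must be binary with both levels present")
  fit_stratum <- function(level) {
    ids <- covariates$subject_id[!is.na(s) & s == level]
    if (length(ids) < 10)
      stop("stratum ", level, " has fewer than 10 subjects")
    trajectory_lmm(long_data[long_data$subject_id %in% ids, ],
                   covariates[covariates$subject_id %in% ids, ],
                   model = "no_reading", estimation = estimation,
                   include_sex = include_sex, age_center = age_center,
                   min_visits = min_visits)
  }
  structure(list(low = fit_stratum(lev[1]), high = fit_stratum(lev[2]),
                 stratum_var = stratum_var, levels = lev),
            class = "stratified_lmm")
}

#' @export
print.stratified_lmm <- function(x, ...) {
  cat("stratified trajectory fits by", x$stratum_var, "\n")
  for (s in c("low", "high")) {
    w <- wald_test(x[[s]], "genotype:age")
    cat(sprintf("  %s (n = %d): genotype:age = %.4f D/yr (SE %.4f), p = %.3g\n",
                s, x[[s]]$n_subjects, w$estimate, w$se, w$p))
  }
  invisible(x)
}

# Methods for traj_lmm --------------------------------------------------------

#' @export
print.traj_lmm <- function(x, ...) {
  cat(sprintf("Refractive trajectory LMM (%s): %d subjects, %d observations\n",
              x$estimation, x$n_subjects, x$n_obs))
  cat(sprintf("log-likelihood %.3f%s\n", x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("fixed effects:\n")
  print(round(x$beta_hat, 5))
  cat(sprintf("random effects: var(intercept) = %.4f D^2, var(age) = %.5f, cov = %.5f; residual = %.4f D^2\n",
              x$G_hat[1, 1], x$G_hat[2, 2], x$G_hat[1, 2], x$sigma2_hat))
  invisible(x)
}

#' @export
coef.traj_lmm <- function(object, ...) object$beta_hat

#' @export
vcov.traj_lmm <- function(object, ...) object$beta_cov

#' @export
logLik.traj_lmm <- function(object, ...) {
  structure(object$loglik,
            df = length(object$beta_hat) + 4,
            nobs = object$n_obs, class = "logLik")
}

#' Summarize a trajectory LMM fit
#'
#' @param object A `traj_lmm`.
#' @param ... Unused.
#' @return A `summary.traj_lmm` with a per-term table (estimate, SE, z, p).
#' @export
summary.traj_lmm <- function(object, ...) {
  tab <- t(vapply(object$terms, function(t) {
    w <- wald_test(object, t)
    c(estimate = w$estimate, se = w$se, z = w$z, p = w$p)
  }, numeric(4)))
  structure(list(fit = object, coefficients = as.data.frame(tab)),
            class = "summary.traj_lmm")
}

#' @export
print.summary.traj_lmm <- function(x, ...) {
  print(x$fit)
  cat("\nterm table:\n")
  print(format(x$coefficients, digits = 4))
  invisible(x)
}

#' Population-level trajectory predictions
#'
#' Fixed-effects-only predictions for new subject profiles across ages.
#'
#' @param object A `traj_lmm`.
#' @param newdata `data.frame` with `age_years` plus any of `sex`,
#'   `genotype`, `reading` required by the fit's terms.
#' @param ... Unused.
#' @return Numeric vector of predicted spherical equivalents (D).
#' @export
predict.traj_lmm <- function(object, newdata, ...) {
  ac <- if (!is.null(object$spec)) object$spec$age_center else 11.5
  a <- newdata$age_years - ac
  get0 <- function(nm) if (nm %in% names(newdata)) newdata[[nm]] else
    stop("newdata lacks column '", nm, "' required by the fit")
  cols <- list(intercept = rep(1, nrow(newdata)), age = a, age2 = a^2,
               age3 = a^3)
  build <- function(term) {
    if (term %in% names(cols)) return(cols[[term]])
    parts <- strsplit(term, ":")[[1]]
    Reduce(`*`, lapply(parts, function(pp)
      if (pp == "age") a else get0(pp)))
  }
  X <- vapply(object$terms, build, numeric(nrow(newdata)))
  drop(X %*% object$beta_hat)
}

#' Marginal residuals of a trajectory fit
#'
#' @param object A `traj_lmm` fitted via [build_design()]/[fit_lmm()] in the
#'   same session (requires the design).
#' @param design The design blocks used for the fit.
#' @param ... Unused.
#' @return Numeric vector `y - X beta_hat` (marginal residuals).
#' @export
residuals.traj_lmm <- function(object, design, ...) {
  drop(design$y - design$X %*% object$beta_hat)
}

#' Simulate from a fitted trajectory model
#'
#' Draws new longitudinal datasets from the fitted fixed effects, random-
#' effect covariance and residual variance, using the default visit schedule.
#' Useful for parametric-bootstrap checks.
#'
#' @param object A `traj_lmm` whose terms include `genotype` (others
#'   optional).
#' @param nsim Number of datasets.
#' @param seed Integer seed.
#' @param n_subjects Subjects per dataset.
#' @param p_carrier Carrier probability.
#' @param p_reading High-reading probability (used when the fit has reading
#'   terms).
#' @param ... Unused.
#' @return A list of `long_phenotypes` objects (length `nsim`).
#' @export
simulate.traj_lmm <- function(object, nsim = 1, seed = NULL,
                              n_subjects = 500, p_carrier = 0.02,
                              p_reading = 0.38, ...) {
  if (!is.null(seed)) set.seed(seed)
  b <- object$beta_hat
  gv <- function(nm) if (nm %in% names(b)) b[[nm]] else 0
  pars <- trajectory_params(
    beta0 = gv("intercept"), beta1 = gv("age"), beta2 = gv("age2"),
    beta3 = gv("age3"), gamma_g = gv("genotype"),
    gamma_ga = gv("genotype:age"), gamma_r = gv("reading"),
    gamma_ra = gv("reading:age"), gamma_gr = gv("genotype:reading"),
    gamma_gra = gv("genotype:reading:age"), beta_sex = gv("sex"),
    g00 = object$G_hat[1, 1], g11 = object$G_hat[2, 2],
    g01 = object$G_hat[1, 2], sigma2_eps = object$sigma2_hat,
    age_center = if (!is.null(object$spec)) object$spec$age_center else 11.5)
  lapply(seq_len(nsim), function(i) {
    g <- stats::rbinom(n_subjects, 1, p_carrier)
    r <- stats::rbinom(n_subjects, 1, p_reading)
    simulate_trajectories(g, r, pars, visit_schedule(),
                          sex = stats::rbinom(n_subjects, 1, 0.5))
  })
}
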
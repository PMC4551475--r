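.reading_low <- c("None at all", "1 hour or less")
.reading_high <- c("1-2 hours", "1–2 hours", "3 or more hours")

.code_exposure <- function(response, what) {
  out <- rep(NA_integer_, length(response))
  ok <- !is.na(response)
  r <- as.character(response[ok])
  valid <- c(.reading_low, .reading_high)
  bad <- setdiff(unique(r), valid)
  if (length(bad))
    stop("unrecognized ", what, " response(s): ",
         paste(shQuote(bad), collapse = ", "),
         "; valid categories are: \"None at all\", \"1 hour or less\", ",
         "\"1–2 hours\", \"3 or more hours\"")
  out[ok] <- as.integer(r %in% .reading_high)
  out
}

#' Code time-spent-reading questionnaire responses
#'
#' Daily time reading books for pleasure is dichotomized: "1-2 hours" and
#' "3 or more hours" code as high (1); "None at all" and "1 hour or less"
#' code as low (0, the reference). Missing responses stay missing and are
#' excluded listwise downstream. Both the en-dash and plain-hyphen spellings
#' of "1-2 hours" are accepted.
#'
#' @param response Character vector of questionnaire categories (or `NA`).
#' @return Integer vector in \{0, 1, NA\}.
#' @examples
#' code_reading(c("None at all", "3 or more hours", NA))
#' @export
code_reading <- function(response) .code_exposure(response, "time-reading")

#' Code time-outdoors questionnaire responses
#'
#' Daily time out of doors in summer, dichotomized with the same category
#' scheme as [code_reading()]: high (1) for "1-2 hours" or "3 or more
#' hours", low (0) otherwise.
#'
#' @inheritParams code_reading
#' @return Integer vector in \{0, 1, NA\}.
#' @export
code_outdoors <- function(response) .code_exposure(response, "time-outdoors")

#' Classify myopia from spherical equivalent
#'
#' Binary myopia status: 1 if the spherical equivalent is at or below the
#' threshold (boundary inclusive), else 0. The default threshold of -0.75 D
#' is a common epidemiological convention; it is a package choice, exposed
#' here, not a value inherited from any particular cohort analysis.
#'
#' @param sph_equiv Spherical equivalent in diopters.
#' @param threshold Myopia cutoff in diopters (default -0.75).
#' @return Integer vector in \{0, 1\} (NA preserved).
#' @export
classify_myopia <- function(sph_equiv, threshold = -0.75) {
  as.integer(sph_equiv <= threshold)
}

#' Logistic regression with odds ratios and Wald intervals
#'
#' Fits outcome ~ intercept + predictors (+ optional interaction between the
#' first two predictor columns) by iteratively reweighted least squares, and
#' reports odds ratios with Wald 95% confidence intervals. Complete
#' separation is detected and flagged as non-convergence rather than
#' returning silently huge coefficients.
#'
#' @param outcome Binary 0/1 vector; both classes must be present.
#' @param predictors Numeric matrix/data.frame of predictors.
#' @param with_interaction If `TRUE`, append the elementwise product of the
#'   first two predictor columns.
#' @return A `gxe_logit`: list with `table` (`term`, `estimate`, `se`, `or`,
#'   `ci_low`, `ci_high`, `p`), `converged`, `n`.
#' @examples
#' x <- rbinom(200, 1, 0.4)
#' y <- rbinom(200, 1, plogis(-1 + x))
#' fit_logistic(y, cbind(exposure = x))
#' @export
fit_logistic <- function(outcome, predictors, with_interaction = FALSE) {
  predictors <- as.matrix(predictors)
  if (is.null(colnames(predictors)))
    colnames(predictors) <- paste0("x", seq_len(ncol(predictors)))
  if (with_interaction) {
    if (ncol(predictors) < 2)
      stop("interaction requires at least two predictor columns")
    predictors <- cbind(predictors,
                        predictors[, 1] * predictors[, 2])
    colnames(predictors)[ncol(predictors)] <-
      paste(colnames(predictors)[1:2], collapse = ":")
  }
  cc <- stats::complete.cases(outcome, predictors)
  y <- outcome[cc]; X <- predictors[cc, , drop = FALSE]
  if (length(unique(y)) < 2)
    stop("outcome must contain both classes")
  if (length(y) <= ncol(X) + 1) stop("too few cases for the predictor count")
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  co <- fit$coefficients
  # covariance from the final IRLS weights
  W <- fit$weights
  XtWX <- crossprod(cbind(1, X) * sqrt(W))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  separated <- is.null(cov) || any(abs(co) > 15) || any(fit$fitted.values > 1 - 1e-10) &&
    any(fit$fitted.values < 1e-10)
  converged <- fit$converged && !separated && !is.null(cov)
  if (!converged)
    warning("logistic fit did not converge cleanly (possible complete ",
            "separation); estimates are unreliable")
  se <- if (is.null(cov)) rep(NA_real_, length(co)) else sqrt(diag(cov))
  z <- co / se
  tab <- data.frame(term = c("(Intercept)", colnames(X)),
                    estimate = unname(co), se = unname(se),
                    or = exp(unname(co)),
                    ci_low = exp(unname(co - 1.96 * se)),
                    ci_high = exp(unname(co + 1.96 * se)),
                    p = 2 * stats::pnorm(abs(unname(z)), lower.tail = FALSE),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, converged = converged, n = length(y)),
            class = "gxe_logit")
}

#' @export
print.gxe_logit <- function(x, ...) {
  cat(sprintf("logistic model, n = %d%s\n", x$n,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], signif, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Incremental variance explained
#'
#' OLS R-squared of a base model and of base + added predictors on the
#' identical complete-case set, with the increment reported in percentage
#' points. Added columns collinear with the base contribute nothing and
#' yield a warning with delta = 0.
#'
#' @param phenotype Numeric outcome (e.g. spherical equivalent, D).
#' @param base Numeric matrix of base predictors (an intercept is always
#'   included automatically; pass `NULL` for intercept-only).
#' @param added Numeric matrix of additional predictors.
#' @return An `r2_report`: list with `r2_base`, `r2_full` (proportions) and
#'   `delta` (percentage points).
#' @export
incremental_r2 <- function(phenotype, base = NULL, added) {
  added <- as.matrix(added)
  if (!is.null(base)) base <- as.matrix(base)
  cc <- stats::complete.cases(phenotype, added,
                              if (is.null(base)) rep(0, length(phenotype)) else base)
  y <- phenotype[cc]
  Xb <- cbind(rep(1, length(y)),
              if (is.null(base)) NULL else base[cc, , drop = FALSE])
  Xf <- cbind(Xb, added[cc, , drop = FALSE])
  r2 <- function(X) {
    f <- stats::lm.fit(X, y)
    1 - sum(f$residuals^2) / sum((y - mean(y))^2)
  }
  r2_base <- r2(Xb)
  qrf <- qr(Xf)
  if (qrf$rank < ncol(Xf)) {
    warning("added column(s) collinear with the base model; delta = 0")
    r2_full <- r2_base
  } else r2_full <- r2(Xf)
  structure(list(r2_base = r2_base, r2_full = max(r2_full, r2_base),
                 delta = 100 * (max(r2_full, r2_base) - r2_base)),
            class = "r2_report")
}

#' @export
print.r2_report <- function(x, ...) {
  cat(sprintf("R^2 base = %.4f (%.2f%%), full = %.4f (%.2f%%), delta = %.2f percentage points\n",
              x$r2_base, 100 * x$r2_base, x$r2_full, 100 * x$r2_full, x$delta))
  invisible(x)
}

#' Cross-sectional gene-environment analysis at a target age
#'
#' Convenience wrapper reproducing the cross-sectional design: takes each
#' subject's refraction at the visit closest to `target_age`, classifies
#' myopia, and fits (i) logistic models for myopia on carrier genotype and a
#' binary exposure, with and without interaction, and (ii) the incremental
#' linear-regression R-squared of adding genotype and the interaction to an
#' exposure-only model of refraction. Age is not included: in a birth cohort
#' the age spread at one clinic visit is narrow.
#'
#' @param long_data,covariates As in [build_design()].
#' @param exposure_var `"reading"` or `"outdoors"` (column of `covariates`).
#' @param target_age Target age in years (default 15.5).
#' @param max_age_gap Widest allowed |visit age - target| (default 1 year).
#' @param myopia_threshold Diopter cutoff for [classify_myopia()].
#' @return A `gxe_crosssec`: list with `logistic_main`,
#'   `logistic_interaction` (`gxe_logit`), `r2` (`r2_report`), `n`, and the
#'   threshold used.
#' @export
crosssec_gxe <- function(long_data, covariates, exposure_var = "reading",
                         target_age = 15.5, max_age_gap = 1,
                         myopia_threshold = -0.75) {
  if (inherits(long_data, "long_phenotypes")) long_data <- long_data$phenotypes
  if (!exposure_var %in% names(covariates))
    stop("exposure variable '", exposure_var, "' not in covariates")
  d <- long_data[abs(long_data$age_years - target_age) <= max_age_gap, ]
  if (nrow(d) == 0) stop("no visits within ", max_age_gap, " years of age ",
                         target_age)
  # closest visit per subject
  d <- d[order(d$subject_id, abs(d$age_years - target_age)), ]
  d <- d[!duplicated(d$subject_id), ]
  idx <- match(d$subject_id, covariates$subject_id)
  g <- covariates$genotype[idx]
  e <- covariates[[exposure_var]][idx]
  keep <- stats::complete.cases(d$sph_equiv_D, g, e)
  d <- d[keep, ]; g <- g[keep]; e <- e[keep]
  myo <- classify_myopia(d$sph_equiv_D, myopia_threshold)
  P <- cbind(genotype = g, exposure = e)
  colnames(P)[2] <- exposure_var
  main <- fit_logistic(myo, P, with_interaction = FALSE)
  inter <- fit_logistic(myo, P, with_interaction = TRUE)
  r2 <- incremental_r2(d$sph_equiv_D, base = cbind(exposure = e),
                       added = cbind(genotype = g, interaction = g * e))
  structure(list(logistic_main = main, logistic_interaction = inter,
                 r2 = r2, n = sum(keep), exposure_var = exposure_var,
                 myopia_threshold = myopia_threshold,
                 target_age = target_age),
            class = "gxe_crosssec")
}

#' @export
print.gxe_crosssec <- function(x, ...) {
  cat(sprintf("cross-sectional G x E at age %.1f y (myopia <= %.2f D; n = %d)\n",
              x$target_age, x$myopia_threshold, x$n))
  cat("-- main-effects logistic model --\n"); print(x$logistic_main)
  cat("-- with interaction --\n"); print(x$logistic_interaction)
  print(x$r2)
  invisible(x)
}
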
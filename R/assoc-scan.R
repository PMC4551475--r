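#' Single-SNP dosage regression
#'
#' Ordinary least squares of a quantitative phenotype on intercept + genotype
#' dosage + covariates, with a two-sided p-value from the t distribution on
#' the residual degrees of freedom. Missing values are handled per SNP by
#' complete-case analysis, so the reported `n` is honest for each SNP.
#'
#' @param dosage Numeric dosage vector (expected allele count, in \[0, 2\]).
#' @param phenotype Numeric phenotype vector (diopters for refraction).
#' @param covariates Optional numeric matrix/data.frame of covariates.
#' @return List with `beta`, `se`, `statistic` (t), `p`, `n` (complete cases).
#' @examples
#' d <- rbinom(50, 2, 0.3)
#' fit_snp_linear(d, 2 - 0.6 * d)
#' @export
fit_snp_linear <- function(dosage, phenotype, covariates = NULL) {
  n0 <- length(dosage)
  if (length(phenotype) != n0)
    stop("dosage and phenotype must have equal length")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n0)
      stop("covariates must have one row per subject")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("covar", seq_len(ncol(covariates)))
  }
  X <- cbind(`(Intercept)` = 1, dosage = as.numeric(dosage), covariates)
  cc <- stats::complete.cases(X, phenotype)
  X <- X[cc, , drop = FALSE]
  y <- as.numeric(phenotype)[cc]
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2)
    stop("insufficient data: need at least ", p + 2, " complete cases, have ", n)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("collinear design: column(s) ", paste(bad, collapse = ", "),
         " linearly dependent on the others")
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  df <- n - p
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  # qr.R columns follow the pivot order; map back to original columns
  se_all <- sqrt(sigma2 * diag(XtXinv))[order(qrX$pivot)]
  b <- beta[["dosage"]]
  se <- se_all[which(colnames(X) == "dosage")]
  tstat <- b / se
  list(beta = unname(b), se = unname(se), statistic = unname(tstat),
       p = 2 * stats::pt(abs(tstat), df, lower.tail = FALSE), n = n)
}

#' Parse a "chr:start-end" region string
#'
#' @param region Either a list/vector `(chrom, start, end)` or a string like
#'   `"11:129904497-129971498"`. The interval is 1-based and closed on both
#'   ends.
#' @return List with `chrom` (character), `start`, `end` (numeric).
#' @export
parse_region <- function(region) {
  if (is.character(region) && length(region) == 1) {
    m <- regmatches(region, regexec("^(chr)?([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) == 0) stop("cannot parse region string: ", region)
    region <- list(chrom = m[3], start = as.numeric(m[4]), end = as.numeric(m[5]))
  } else {
    region <- as.list(region)
    names(region) <- c("chrom", "start", "end")
    region$chrom <- sub("^chr", "", as.character(region$chrom))
    region$start <- as.numeric(region$start)
    region$end <- as.numeric(region$end)
  }
  if (region$end < region$start) stop("region end precedes start")
  region
}

#' Region-wide single-SNP association scan
#'
#' Applies [fit_snp_linear()] to every SNP whose position falls in the closed
#' interval `region`. Monomorphic SNPs (no dosage variation among complete
#' cases) are skipped and logged rather than producing degenerate fits.
#' Results are ordered by position regardless of input order.
#'
#' @param genotypes A `genotype_matrix` from [simulate_genotypes()] or
#'   [read_genotypes()].
#' @param phenotype Numeric phenotype vector aligned with the subjects.
#' @param covariates Optional covariate matrix.
#' @param region Region as in [parse_region()]; default spans all SNPs.
#' @return A `region_scan`: list with `results` (position-ordered
#'   `data.frame`: `snp_id`, `chrom`, `pos`, `beta`, `se`, `statistic`, `p`,
#'   `n`), `skipped` (`snp_id`, `reason`), and `region`.
#' @export
scan_region <- function(genotypes, phenotype, covariates = NULL, region = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  snps <- genotypes$snps
  if (is.null(region)) {
    region <- list(chrom = snps$chrom[1], start = min(snps$pos),
                   end = max(snps$pos))
  } else region <- parse_region(region)
  sel <- which(snps$chrom == region$chrom &
                 snps$pos >= region$start & snps$pos <= region$end)
  if (length(sel) == 0)
    stop("empty region: no SNPs overlap ", region$chrom, ":",
         region$start, "-", region$end)
  sel <- sel[order(snps$pos[sel])]
  res <- vector("list", length(sel))
  skipped <- list()
  for (k in seq_along(sel)) {
    j <- sel[k]
    d <- genotypes$dosage[, j]
    cc <- stats::complete.cases(d, phenotype,
                                if (is.null(covariates)) rep(0, length(d)) else covariates)
    if (length(unique(d[cc])) < 2) {
      skipped[[length(skipped) + 1]] <-
        data.frame(snp_id = snps$snp_id[j], reason = "monomorphic",
                   stringsAsFactors = FALSE)
      next
    }
    f <- fit_snp_linear(d, phenotype, covariates)
    res[[k]] <- data.frame(snp_id = snps$snp_id[j], chrom = snps$chrom[j],
                           pos = snps$pos[j], beta = f$beta, se = f$se,
                           statistic = f$statistic, p = f$p, n = f$n,
                           stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(results))
    results <- data.frame(snp_id = character(), chrom = character(),
                          pos = integer(), beta = numeric(), se = numeric(),
                          statistic = numeric(), p = numeric(), n = integer(),
                          stringsAsFactors = FALSE)
  rownames(results) <- NULL
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(snp_id = character(), reason = character(), stringsAsFactors = FALSE)
  structure(list(results = results, skipped = skipped, region = region),
            class = "region_scan")
}

#' @export
print.region_scan <- function(x, ...) {
  cat(sprintf("region_scan %s:%d-%d: %d SNPs tested, %d skipped\n",
              x$region$chrom, x$region$start, x$region$end,
              nrow(x$results), nrow(x$skipped)))
  if (nrow(x$results)) {
    top <- x$results[which.min(x$results$p), ]
    cat(sprintf("top SNP %s: beta = %.3f D (SE %.3f), p = %.3g, n = %d\n",
                top$snp_id, top$beta, top$se, top$p, top$n))
  }
  invisible(x)
}

#' QQ-plot coordinates for a set of p-values
#'
#' Expected quantiles use the plotting position (i - 0.5)/m for rank i of m;
#' observed values are the sorted p-values, both on the -log10 scale, ready
#' for an expected-vs-observed quantile-quantile plot.
#'
#' @param pvalues Numeric vector of p-values in (0, 1\].
#' @return `data.frame` with columns `expected` and `observed` (-log10),
#'   ordered from the most significant p-value down.
#' @examples
#' qq_points(c(0.01, 0.5))
#' @export
qq_points <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (length(pvalues) == 0) stop("empty p-value list")
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]; floor zero p-values before calling")
  m <- length(pvalues)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = -log10(sort(pvalues)))
}

#' Plot a region scan
#'
#' Two-panel base-graphics display: -log10 p by position, and the QQ plot
#' from [qq_points()].
#'
#' @param x A `region_scan`.
#' @param ... Passed to `plot`.
#' @export
plot.region_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  r <- x$results
  plot(r$pos / 1e6, -log10(r$p), xlab = "position (Mb)",
       ylab = expression(-log[10](p)), pch = 19, ...)
  q <- qq_points(r$p)
  plot(q$expected, q$observed, xlab = expression(Expected ~ -log[10](p)),
       ylab = expression(Observed ~ -log[10](p)), pch = 19, ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

# Fast scan machinery for permutation testing -------------------------------
#
# For complete data the per-SNP OLS t-test is computed by Frisch-Waugh
# residualization: phenotype and every dosage column are residualized against
# [1, covariates] once, after which each SNP's beta, t and p come from a
# single cross-product. This is algebraically identical to refitting the full
# model per SNP (equality is covered by tests) but turns a B-permutation
# regional scan into B matrix-vector products.

# Precompute the pieces that do not change across permutations.
.scan_precompute <- function(dosage, covariates = NULL) {
  n <- nrow(dosage)
  C <- cbind(rep(1, n), covariates)
  qrC <- qr(C)
  Gres <- qr.resid(qrC, dosage)
  gss <- colSums(Gres^2)
  keep <- gss >= 1e-12 * n       # drop monomorphic / covariate-collinear SNPs
  df <- n - ncol(C) - 1L
  list(qrC = qrC, Gres = Gres[, keep, drop = FALSE], gss = gss[keep],
       keep = keep, df = df)
}

# Per-SNP two-sided p-values for one phenotype vector.
.scan_pvalues <- function(pre, y) {
  yres <- qr.resid(pre$qrC, y)
  yss <- sum(yres^2)
  xy <- drop(crossprod(pre$Gres, yres))
  gss <- pre$gss
  rss <- pmax(yss - xy^2 / gss, 0)
  t2 <- xy^2 / gss * pre$df / rss
  stats::pf(t2, 1, pre$df, lower.tail = FALSE)
}
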
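#' Low-order percentile of a p-value set
#'
#' Order-statistic convention without interpolation: returns the k-th
#' smallest value with k = ceiling(q * m). With the default q = 0.05 this is
#' the "5th percentile p-value" summarizing an excess of low p-values across
#' a region.
#'
#' @param pvalues Non-empty numeric vector.
#' @param q Quantile level in (0, 1).
#' @return The k-th smallest p-value.
#' @examples
#' percentile_p(runif(100), 0.05) # 5th smallest
#' @export
percentile_p <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0) stop("empty p-value list")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  sort(pvalues)[ceiling(q * length(pvalues))]
}

.region_statistic <- function(pvals, statistic, q) {
  switch(statistic,
         min_p = min(pvals),
         percentile_p = percentile_p(pvals, q),
         stop("unknown statistic kind: ", statistic))
}

# all permutations of 1..n, as a n! x n matrix (n <= 8 guarded by caller)
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub), n - 1L)
    r <- r + nrow(sub)
  }
  out
}

#' Phenotype-permutation regional association test
#'
#' Assesses whether a region's single-SNP association results are more
#' extreme than expected under no genotype-phenotype association, accounting
#' for multiple testing and LD between markers. Subjects are assigned a new
#' phenotype sampled randomly without replacement from the true phenotypes
#' (covariates and genotypes stay attached to their subjects), the full
#' regional scan is recomputed, and the chosen summary statistic — the
#' minimum p-value, or a low-order percentile p-value capturing an excess of
#' low p-values — is recorded. The empirical p-value uses the add-one
#' estimator (r + 1)/(B + 1), which never returns 0 and is valid by
#' construction; ties count as extreme.
#'
#' @param genotypes A `genotype_matrix`.
#' @param phenotype Numeric phenotype vector.
#' @param covariates Optional covariate matrix.
#' @param region Region (see [parse_region()]); default all SNPs.
#' @param statistic `"min_p"` or `"percentile_p"`.
#' @param q Percentile level when `statistic = "percentile_p"`.
#' @param B Number of permutations (default 1000). A warning is issued below
#'   B = 19 since the attainable resolution then exceeds 0.05.
#' @param seed Integer seed; the permutation stream is reproducible.
#' @param exhaustive If `TRUE`, enumerate all n! distinct permutations
#'   (requires n <= 8) and report the exact proportion.
#' @return A `regional_test`: list with `statistic_kind`, `q`, `observed`,
#'   `perm_values`, `empirical_p`, `B`, `seed`, `exhaustive`.
#' @export
permutation_region_test <- function(genotypes, phenotype, covariates = NULL,
                                    region = NULL,
                                    statistic = c("min_p", "percentile_p"),
                                    q = 0.05, B = 1000, seed = NULL,
                                    exhaustive = FALSE) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(genotypes, "genotype_matrix"))
  n <- length(phenotype)
  if (anyNA(phenotype) || (!is.null(covariates) && anyNA(covariates)) ||
      anyNA(genotypes$dosage))
    stop("permutation test requires complete data; drop incomplete subjects first")
  if (exhaustive && n > 8)
    stop("exhaustive enumeration limited to n <= 8 subjects (n! permutations)")
  if (!exhaustive && B < 1) stop("B must be >= 1")
  if (!exhaustive && B < 19)
    warning("B = ", B, " permutations: empirical p resolution ",
            signif(1 / (B + 1), 3), " exceeds 0.05")

  if (stats::var(phenotype) == 0) {
    warning("constant phenotype: all permutation statistics tie; empirical_p = 1")
    return(structure(list(statistic_kind = statistic, q = q, observed = NA_real_,
                          perm_values = rep(NA_real_, if (exhaustive) factorial(n) else B),
                          empirical_p = 1, B = if (exhaustive) factorial(n) else B,
                          seed = seed, exhaustive = exhaustive),
                     class = "regional_test"))
  }

  # observed statistic from the reference scan path
  scan <- scan_region(genotypes, phenotype, covariates, region)
  if (nrow(scan$results) == 0) stop("no polymorphic SNPs in region")
  observed <- .region_statistic(scan$results$p, statistic, q)
  # ties count as extreme; a hair of relative tolerance keeps permutations
  # that merely reorder floating-point sums classified as ties
  tie_cut <- observed * (1 + 1e-9)

  # permutations use the residualization fast path (identical algebra)
  region_p <- parse_region(if (is.null(region))
    sprintf("%s:%d-%d", scan$region$chrom, scan$region$start, scan$region$end)
    else region)
  snps <- genotypes$snps
  sel <- which(snps$chrom == region_p$chrom & snps$pos >= region_p$start &
                 snps$pos <= region_p$end)
  pre <- .scan_precompute(genotypes$dosage[, sel, drop = FALSE],
                          if (is.null(covariates)) NULL else as.matrix(covariates))

  if (exhaustive) {
    perms <- .all_perms(n)
    perm_values <- apply(perms, 1L, function(ix)
      .region_statistic(.scan_pvalues(pre, phenotype[ix]), statistic, q))
    empirical_p <- mean(perm_values <= tie_cut)
    B <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    perm_values <- vapply(seq_len(B), function(b)
      .region_statistic(.scan_pvalues(pre, sample(phenotype)), statistic, q),
      numeric(1))
    empirical_p <- (sum(perm_values <= tie_cut) + 1) / (B + 1)
  }
  structure(list(statistic_kind = statistic, q = q, observed = observed,
                 perm_values = perm_values, empirical_p = empirical_p,
                 B = B, seed = seed, exhaustive = exhaustive),
            class = "regional_test")
}

#' @export
print.regional_test <- function(x, ...) {
  kind <- if (x$statistic_kind == "percentile_p")
    sprintf("percentile p (q = %g)", x$q) else "minimum p"
  cat(sprintf("regional permutation test (%s, %s)\n",
              kind, if (x$exhaustive) "exhaustive" else paste0("B = ", x$B)))
  cat(sprintf("observed statistic = %.4g, empirical p = %.4g\n",
              x$observed, x$empirical_p))
  invisible(x)
}

#' Kolmogorov-Smirnov comparison of regional p-values
#'
#' Compares the distribution of p-values inside a candidate region with those
#' in its surroundings (two-sample mode), or with the uniform distribution
#' expected under no association (`vs_uniform` mode). D is the supremum
#' absolute difference of the empirical CDFs; the p-value uses the asymptotic
#' Kolmogorov distribution. Small samples (min n < 10) are flagged since the
#' asymptotic reference is then rough.
#'
#' @param inside_p P-values for SNPs inside the region.
#' @param outside_p P-values for surrounding SNPs (two-sample mode); ignored
#'   when `mode = "vs_uniform"`.
#' @param mode `"two_sample"` or `"vs_uniform"`.
#' @return A `ks_result`: list with `D`, `p`, `n_inside`, `n_outside`, `mode`.
#' @export
ks_region_comparison <- function(inside_p, outside_p = NULL,
                                 mode = c("two_sample", "vs_uniform")) {
  mode <- match.arg(mode)
  chk <- function(x, nm) {
    if (length(x) == 0) stop(nm, " must be non-empty")
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop(nm, " must lie in [0, 1]")
  }
  chk(inside_p, "inside_p")
  if (mode == "two_sample") {
    chk(outside_p, "outside_p")
    if (min(length(inside_p), length(outside_p)) < 10)
      warning("fewer than 10 p-values in a group: asymptotic KS p is rough")
    # ties between empirical p-values are expected; the asymptotic p is used
    kt <- suppressWarnings(stats::ks.test(inside_p, outside_p, exact = FALSE))
    n_out <- length(outside_p)
  } else {
    if (length(inside_p) < 10)
      warning("fewer than 10 p-values: asymptotic KS p is rough")
    kt <- suppressWarnings(stats::ks.test(inside_p, "punif", exact = FALSE))
    n_out <- NA_integer_
  }
  structure(list(D = unname(kt$statistic), p = kt$p.value,
                 n_inside = length(inside_p), n_outside = n_out, mode = mode),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("Kolmogorov-Smirnov %s: D = %.4g, p = %.4g (n = %d%s)\n",
              x$mode, x$D, x$p, x$n_inside,
              if (is.na(x$n_outside)) "" else paste0(" vs ", x$n_outside)))
  invisible(x)
}

#' Split summary statistics into inside/outside p-value sets
#'
#' Assigns every SNP in the flanked window to exactly one set: `inside` for
#' positions within the closed region, `outside` for positions within
#' region +/- flank but not inside. SNPs beyond the flank are excluded.
#'
#' @param summary_stats `data.frame` with columns `chrom` (optional), `pos`
#'   and `p`.
#' @param region Region (see [parse_region()]).
#' @param flank Flank width in bp on each side (default 100 kb).
#' @return List with numeric vectors `inside_p` and `outside_p`.
#' @export
split_region_pvalues <- function(summary_stats, region, flank = 100000) {
  region <- parse_region(region)
  if (!all(c("pos", "p") %in% names(summary_stats)))
    stop("summary_stats must have columns pos and p")
  ss <- summary_stats
  if ("chrom" %in% names(ss))
    ss <- ss[sub("^chr", "", as.character(ss$chrom)) == region$chrom, ]
  inside <- ss$pos >= region$start & ss$pos <= region$end
  inwin <- ss$pos >= region$start - flank & ss$pos <= region$end + flank
  if (!any(inside)) stop("no SNPs inside the region")
  list(inside_p = ss$p[inside], outside_p = ss$p[inwin & !inside])
}
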
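test_that("percentile_p follows the ceiling(q*m) order-statistic convention", {
  set.seed(1)
  p20 <- runif(20)
  expect_equal(percentile_p(p20, 0.05), min(p20))
  p100 <- runif(100)
  expect_equal(percentile_p(p100, 0.05), sort(p100)[5])  # sort-based oracle
  expect_equal(percentile_p(rep(0.7, 13), 0.31), 0.7)
  expect_error(percentile_p(numeric(0)), "empty")
})

test_that("a constant phenotype degenerates to empirical p = 1", {
  g <- simulate_genotypes(30, make_block_snps(3), seed = 2)
  expect_warning(r <- permutation_region_test(g, rep(1.5, 30), B = 25),
                 "constant")
  expect_equal(r$empirical_p, 1)
})

test_that("small B triggers a resolution warning", {
  g <- simulate_genotypes(40, make_block_snps(3), seed = 3)
  expect_warning(permutation_region_test(g, rnorm(40), B = 9), "resolution")
})

test_that("exhaustive enumeration at n = 5 matches a brute-force lm oracle", {
  set.seed(4)
  g <- simulate_genotypes(5, make_block_snps(3, risk_raf = 0.4, raf = 0.4),
                          seed = 5)
  # ensure polymorphism in this tiny draw
  while (any(apply(g$dosage, 2, function(x) length(unique(x))) < 2))
    g <- simulate_genotypes(5, make_block_snps(3, risk_raf = 0.4, raf = 0.4),
                            seed = sample.int(1e6, 1))
  y <- rnorm(5)
  r <- permutation_region_test(g, y, statistic = "min_p", exhaustive = TRUE)
  # oracle: enumerate permutations recursively (independent code path) and
  # compute each min p by the closed-form correlation t-test
  perms <- rbind(do.call(rbind, lapply(combinat_perms(1:5), rbind)))
  stat <- apply(perms, 1, function(ix)
    min(vapply(1:3, function(j) oracle_simple_p(g$dosage[, j], y[ix]),
               numeric(1))))
  obs <- min(vapply(1:3, function(j) oracle_simple_p(g$dosage[, j], y),
                    numeric(1)))
  expect_equal(r$B, factorial(5))
  expect_equal(r$observed, obs, tolerance = 1e-12)
  # ties count as extreme (same hairline tolerance as the implementation, so
  # permutations that only reorder floating-point sums classify identically)
  expect_equal(r$empirical_p, mean(stat <= obs * (1 + 1e-9)),
               tolerance = 1e-12)
})

test_that("exhaustive and Monte-Carlo modes agree within Monte-Carlo error", {
  set.seed(6)
  g <- simulate_genotypes(6, make_block_snps(3, risk_raf = 0.4, raf = 0.4),
                          seed = 7)
  y <- rnorm(6)
  ex <- permutation_region_test(g, y, statistic = "min_p", exhaustive = TRUE)
  mc <- permutation_region_test(g, y, statistic = "min_p", B = 4000, seed = 8)
  se <- sqrt(ex$empirical_p * (1 - ex$empirical_p) / 4000)
  expect_lt(abs(mc$empirical_p - ex$empirical_p), 3 * se + 1 / 4001)
})

test_that("the permutation stream is reproducible and p lies on its grid", {
  g <- simulate_genotypes(80, make_block_snps(5), seed = 9)
  y <- rnorm(80)
  r1 <- permutation_region_test(g, y, B = 60, seed = 10)
  r2 <- permutation_region_test(g, y, B = 60, seed = 10)
  expect_identical(r1$perm_values, r2$perm_values)
  expect_gte(r1$empirical_p, 1 / 61)
  expect_lte(r1$empirical_p, 1)
  expect_length(r1$perm_values, 60)
})

test_that("empirical p decreases as the observed association strengthens", {
  snps <- make_block_snps(10, risk_index = 5, risk_raf = 0.3)
  set.seed(11)
  g <- simulate_genotypes(300, snps, ld_rho = 0.3)
  noise <- rnorm(300)
  p_at <- vapply(c(0, 0.2, 0.5), function(b) {
    y <- -b * g$dosage[, 5] + noise
    permutation_region_test(g, y, statistic = "min_p", B = 199,
                            seed = 12)$empirical_p
  }, numeric(1))
  expect_true(all(diff(p_at) <= 0))
})

test_that("KS comparison handles boundary cases and matches a CDF oracle", {
  same <- c(0.1, 0.4, 0.9)
  expect_warning(r0 <- ks_region_comparison(same, same), "fewer than 10")
  expect_equal(r0$D, 0)
  expect_equal(r0$p, 1)
  r1 <- suppressWarnings(
    ks_region_comparison(c(0.01, 0.05, 0.09), c(0.91, 0.95, 0.99)))
  expect_equal(r1$D, 1)
  # brute-force double-loop supremum of |F_in - F_out|
  inside <- c(0.01, 0.04, 0.3)
  outside <- c(0.2, 0.5, 0.8, 0.9)
  grid <- sort(c(inside, outside))
  D_oracle <- max(vapply(grid, function(t)
    abs(mean(inside <= t) - mean(outside <= t)), numeric(1)))
  r2 <- suppressWarnings(ks_region_comparison(inside, outside))
  expect_equal(r2$D, D_oracle)
  expect_error(ks_region_comparison(c(0.2, 1.4), c(0.1)), "lie in")
})

test_that("vs-uniform mode tests against the U(0,1) CDF", {
  set.seed(13)
  p <- runif(200)
  r <- ks_region_comparison(p, mode = "vs_uniform")
  expect_equal(r$D, unname(suppressWarnings(ks.test(p, "punif")$statistic)))
  expect_gt(r$p, 0.01)
  skew <- runif(200)^3
  expect_lt(ks_region_comparison(skew, mode = "vs_uniform")$p, 1e-6)
})

test_that("split_region_pvalues partitions the flanked window exactly", {
  ss <- data.frame(pos = c(90, 150, 200, 260), p = c(0.1, 0.2, 0.3, 0.4))
  sp <- split_region_pvalues(ss, list("1", 100, 200), flank = 50)
  expect_equal(sp$inside_p, c(0.2, 0.3))  # boundary SNP at end is inside
  expect_equal(sp$outside_p, 0.1)          # 260 lies beyond the flank
  expect_error(split_region_pvalues(data.frame(pos = 5, p = 0.1),
                                    list("1", 100, 200)), "inside")
  # counting property on a random table
  set.seed(14)
  tab <- data.frame(pos = sample.int(1e6, 500), p = runif(500))
  reg <- list("1", 4e5, 6e5)
  sp2 <- split_region_pvalues(tab, reg, flank = 1e5)
  expect_equal(length(sp2$inside_p) + length(sp2$outside_p),
               sum(tab$pos >= 3e5 & tab$pos <= 7e5))
})
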
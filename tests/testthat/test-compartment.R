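# Window densities and the compartment statistics battery.

test_that("window feature density unions overlapping features", {
  win <- tibble::tibble(chrom = "c", start = 0L, end = 100L,
                        partial = FALSE)
  ann <- tibble::tibble(
    feature_id = c("g1", "r1", "r2"),
    chrom = "c", start = c(0L, 10L, 30L), end = c(100L, 70L, 90L),
    strand = "+", type = c("gene", "repeat", "repeat"),
    compartment = "none")
  d <- window_feature_density(ann, win, "gene")
  expect_equal(d$gene_fraction, 1)
  # two overlapping repeats covering 80 distinct bp of a 100-bp window
  d <- window_feature_density(ann, win, "repeat")
  expect_equal(d$repeat_fraction, 0.8)
  d <- window_feature_density(ann[0, ], win, "repeat")
  expect_equal(d$repeat_fraction, 0)
})

test_that("wilcoxon test is exact for small untied samples", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")

  r <- wilcoxon_rank_sum(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(r$p, 1)

  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")

  # full enumeration oracle for small untied inputs
  set.seed(24)
  for (i in 1:8) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    vals <- sample(100, na + nb)  # distinct -> no ties
    a <- vals[1:na]; b <- vals[(na + 1):(na + nb)]
    r <- wilcoxon_rank_sum(a, b)
    combs <- utils::combn(na + nb, na)
    ranks <- rank(c(a, b))
    wobs <- sum(ranks[1:na]) - na * (na + 1) / 2
    wall <- apply(combs, 2, function(ix) {
      sum(rank(c(a, b))[ix]) - na * (na + 1) / 2
    })
    mu <- na * nb / 2
    p_enum <- min(1, 2 * min(mean(wall <= wobs), mean(wall >= wobs)))
    expect_equal(r$p, p_enum, tolerance = 1e-12)
  }
})

test_that("BH adjustment is monotone, capped and order-preserving", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(25)
  for (i in 1:5) {
    p <- runif(sample(3:20, 1))
    adj <- bh_fdr(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= 0))  # order-preserving
    expect_equal(bh_fdr(rep(adj[1], 4)), rep(adj[1], 4))  # flat fixed point
  }
  expect_error(bh_fdr(c(0, 0.2)), "0, 1")
})

test_that("permutation p-values are seeded, valid and converge", {
  cfg <- enrichment_config(n_perm = 999, seed = 7)
  x <- c(rnorm(10), rnorm(10))
  lab <- rep(c("a", "b"), each = 10)

  r1 <- permutation_test(x, lab, cfg)
  r2 <- permutation_test(x, lab, cfg)
  expect_identical(r1$p, r2$p)
  expect_gt(r1$p, 0)

  # identical groups: p near 1
  same <- rep(c(5, 6, 7, 8), 2)
  r <- permutation_test(same, rep(c("a", "b"), each = 4), cfg)
  expect_gt(r$p, 0.5)

  # disjoint ranges reach the minimal attainable p
  r <- permutation_test(c(1:10, 101:110), rep(c("a", "b"), each = 10),
                        cfg)
  expect_equal(r$p, 1 / (999 + 1))

  expect_error(permutation_test(1:4, rep("a", 4)), "two levels")
})

test_that("orthologue depletion chi-square matches hand arithmetic", {
  r <- orthologue_depletion_test(c(c1 = 90, c2 = 10),
                                 c(c1 = 100, c2 = 100))
  expect_equal(r$statistic, c(64, 64))
  expect_equal(r$expected, c(50, 50))
  expect_true(r$depleted[2])
  expect_equal(r$p_adj, bh_fdr(r$p))

  r0 <- orthologue_depletion_test(c(c1 = 30, c2 = 60),
                                  c(c1 = 100, c2 = 200))
  expect_equal(r0$statistic, c(0, 0))
  expect_equal(r0$p, c(1, 1))
})

test_that("standardized residuals match the closed form and chisq.test", {
  tab <- matrix(c(10, 20, 20, 10), 2, byrow = TRUE)
  r <- pearson_std_residuals(tab)
  expect_equal(r$residuals[1, 1], -2.582, tolerance = 1e-3)
  expect_true(all(r$flagged))
  # independent cross-check against the stats implementation
  expect_equal(unname(r$residuals),
               unname(chisq.test(tab, correct = FALSE)$stdres),
               tolerance = 1e-12)

  indep <- matrix(c(10, 20, 30, 60), 2, byrow = TRUE)
  r0 <- pearson_std_residuals(indep)
  expect_equal(unname(r0$residuals), matrix(0, 2, 2), tolerance = 1e-12)
  expect_false(any(r0$flagged))
})

test_that("R-squared comes from ordinary least squares", {
  x <- 1:10
  expect_equal(linreg_r2(x, 2 * x + 3), 1)
  expect_warning(r <- linreg_r2(x, rep(5, 10)), "constant")
  expect_true(is.na(r))
  # 4-point hand example via the normal equations
  x <- c(0, 1, 2, 4); y <- c(1, 2, 2, 5)
  beta <- solve(t(cbind(1, x)) %*% cbind(1, x), t(cbind(1, x)) %*% y)
  pred <- cbind(1, x) %*% beta
  r2_hand <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(linreg_r2(x, y), r2_hand, tolerance = 1e-12)
})

test_that("2x2 enrichment chi-square and activity threshold behave", {
  prop <- matrix(c(10, 20, 30, 60), 2, byrow = TRUE)
  expect_equal(sbg_compartment_enrichment(prop)$p, 1, tolerance = 1e-12)
  skew <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  ct <- chisq.test(skew, correct = FALSE)
  expect_equal(sbg_compartment_enrichment(skew)$statistic,
               unname(ct$statistic))
  expect_error(sbg_compartment_enrichment(matrix(c(0, 0, 5, 5), 2)),
               "zero margin")

  expect_false(expression_active(3))   # log2(4) = 2 is not > 2
  expect_true(expression_active(7))
  expect_false(expression_active(0))
  expect_error(expression_active(-1), ">= 0")
})

test_that("per-autosome contrasts apply BH within a feature", {
  set.seed(26)
  wft <- tibble::tibble(
    chrom = rep(c("a1", "a2", "chrUV"), each = 30),
    repeat_fraction = c(runif(30, 0, 0.2), runif(30, 0, 0.2),
                        runif(30, 0.3, 0.6)))
  res <- autosome_vs_sex_tests(wft, "repeat_fraction")
  expect_equal(nrow(res), 2L)
  expect_true(all(res$p_adj < 0.01))
  expect_equal(res$p_adj, bh_fdr(res$p))
})

test_that("compartment contrasts reject under enrichment, hold size under null", {
  set.seed(27)
  # enrichment built in: younger (higher) TRG age ranks on the sex
  # chromosome; both tests should reject at FDR < 0.01
  sex_ages <- sample(5:8, 120, replace = TRUE)
  auto_ages <- sample(1:8, 240, replace = TRUE)
  w <- wilcoxon_rank_sum(sex_ages, auto_ages)
  pt <- permutation_test(c(sex_ages, auto_ages),
                         rep(c("sex", "auto"), c(120, 240)),
                         enrichment_config(n_perm = 2000, seed = 3))
  expect_lt(max(bh_fdr(c(w$p, pt$p))), 0.01)

  # null calibration: rejection rate at alpha = 0.05 within +/- 2%
  reps <- 1000
  rej <- vapply(seq_len(reps), function(i) {
    a <- sample(1:8, 40, replace = TRUE)
    b <- sample(1:8, 40, replace = TRUE)
    wilcoxon_rank_sum(a, b)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})
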
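test_that("dominance analysis matches the independent all-subsets oracle", {
  for (seed in 1:3) {
    dat <- phidyn:::with_seed(seed, {
      x <- matrix(rnorm(40 * 4), 40, 4)
      y <- x %*% c(0.8, 0.4, -0.3, 0) + rnorm(40)
      list(x = x, y = drop(y))
    })
    d <- dominance_analysis(dat$x, dat$y)
    oracle <- dominance_oracle(dat$x, dat$y)
    expect_lt(max(abs(d$importance - oracle)), 1e-10)
    expect_equal(sum(d$importance), d$total_r2, tolerance = 1e-10)
    expect_equal(sum(d$percent_importance), 100, tolerance = 1e-6)
  }
})

test_that("orthogonal predictors get their marginal R-squared as importance", {
  x1 <- rep(c(-1, 1), 32)
  x2 <- rep(c(-1, -1, 1, 1), 16)
  y <- phidyn:::with_seed(5, drop(sqrt(0.3) * x1 + sqrt(0.1) * x2 + rnorm(64, 0, 0.8)))
  d <- dominance_analysis(cbind(a = x1, b = x2), y)
  expect_equal(unname(d$importance[1]), cor(x1, y)^2, tolerance = 1e-12)
  expect_equal(unname(d$importance[2]), cor(x2, y)^2, tolerance = 1e-12)
})

test_that("dominance analysis rejects degenerate designs", {
  x <- matrix(rnorm(30), 30, 1)
  expect_error(dominance_analysis(x, rnorm(30)), "two predictors")
  xc <- cbind(x, x * 2)
  expect_error(dominance_analysis(xc, rnorm(30)), "collinear")
  expect_error(dominance_analysis(matrix(rnorm(20 * 16), 20, 16), rnorm(20)))
})

test_that("permutation R2 test is exact for a perfect fit and reproducible", {
  x <- phidyn:::with_seed(6, matrix(rnorm(30 * 2), 30, 2))
  y <- drop(x %*% c(1, -2))
  res <- permutation_r2_test(x, y, n_perm = 999, seed = 7)
  expect_equal(res$p_value, 1 / 1000)
  res2 <- permutation_r2_test(x, y, n_perm = 999, seed = 7)
  expect_identical(res$p_value, res2$p_value)
  expect_error(permutation_r2_test(x, y, n_perm = 50), ">= 99")
})

test_that("permutation p-values are roughly uniform under the null", {
  ps <- vapply(1:20, function(i) {
    dat <- phidyn:::with_seed(100 + i, list(x = matrix(rnorm(40 * 3), 40, 3),
                                            y = rnorm(40)))
    permutation_r2_test(dat$x, dat$y, n_perm = 199, seed = i)$p_value
  }, 0)
  expect_gt(mean(ps), 0.2)   # not systematically anti-conservative
  expect_lt(mean(ps), 0.8)
  expect_lte(mean(ps < 0.05), 0.25)
})

test_that("spatially constrained correlation honours sign and rank invariance", {
  coords <- tiny_coords(30, seed = 8)
  w <- spatial_weight_matrix(coords)
  a <- spatial_map(coords, 0.4, seed = 9)
  mono <- regional_map(exp(a$values))        # monotone transform
  res <- spatial_corr_msr(a, mono, w, n_surr = 99, seed = 10)
  expect_equal(res$rho, 1)
  neg <- regional_map(-a$values)
  expect_equal(spatial_corr_msr(a, neg, w, n_surr = 99, seed = 11)$rho, -1)
  expect_error(spatial_corr_msr(regional_map(rep(1, 30)), a, w), "constant")
})

test_that("spatial correlation test is calibrated for independent maps", {
  coords <- tiny_coords(25, seed = 12)
  w <- spatial_weight_matrix(coords)
  ps <- vapply(1:20, function(i) {
    a <- spatial_map(coords, 0.4, seed = 200 + i)
    b <- spatial_map(coords, 0.4, seed = 400 + i)
    spatial_corr_msr(a, b, w, n_surr = 99, seed = i)$p_null
  }, 0)
  expect_gte(mean(ps > 0.05), 0.75)
})

test_that("cross-species ranking recovers consistent extremes", {
  # single species: ordering reduces to |z-scored rank|
  one <- matrix(rnorm(20), 1, 20, dimnames = list("sp", paste0("g", 1:20)))
  r <- cross_species_gene_rank(one)
  z <- abs(scale(rank(one[1, ]))[, 1])
  expect_equal(r$score, unname(sort(z, decreasing = TRUE)), tolerance = 1e-12)
  # a gene most-negative in every species tops the list
  tab <- phidyn:::with_seed(13, matrix(rnorm(3 * 30), 3, 30))
  colnames(tab) <- paste0("g", 1:30)
  tab[, "g7"] <- c(-5, -6, -4)
  expect_equal(cross_species_gene_rank(tab)$gene[1], "g7")
  tab[, "g7"] <- c(5, 6, 4)      # consistently extreme positive also wins
  expect_equal(cross_species_gene_rank(tab)$gene[1], "g7")
  tab[1, 3] <- NA
  expect_error(cross_species_gene_rank(tab), "missing")
})

test_that("planted extreme gene is recovered among noise genes", {
  hits <- vapply(1:50, function(i) {
    tab <- phidyn:::with_seed(i, {
      m <- matrix(rnorm(3 * 81), 3, 81)
      m[, 81] <- c(-3.5, -3.5, -3.5) + rnorm(3, sd = 0.2)
      m
    })
    colnames(tab) <- paste0("g", 1:81)
    cross_species_gene_rank(tab)$gene[1] == "g81"
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("sigmoid normalization is a monotone map into (0, 1)", {
  x <- c(-3, 0, 0.5, 2, 10)
  m <- sigmoid_normalize(regional_map(x))
  expect_true(all(m$values > 0 & m$values < 1))
  expect_identical(order(m$values), order(x))
  sym <- sigmoid_normalize(regional_map(c(-2, -1, 0, 1, 2)))
  expect_equal(unname(sym$values[3]), 0.5)
  expect_error(sigmoid_normalize(regional_map(rep(1, 5))), "constant")
})

test_that("BH adjustment matches the hand-applied step-up", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.2), 0.2)
  expect_equal(fdr_bh(rep(0.07, 5)), rep(0.07, 5))
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
})
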
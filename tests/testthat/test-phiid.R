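test_that("gaussian_mi matches the bivariate closed form and the entropy identity", {
  r <- 0.5
  jc <- diag(4)
  jc[1, 3] <- jc[3, 1] <- r          # only X_past correlates with X_future
  m <- lagged_model_from_cov(jc, c(1, 1))
  expect_equal(gaussian_mi(m, 1, 3), -0.5 * log(1 - r^2), tolerance = 1e-12)
  expect_lt(abs(gaussian_mi(m, 2, 4)), 1e-12)
  # I(a;b) = H(a) + H(b) - H(a,b) with Gaussian entropies
  s <- m$joint_cov
  h <- function(idx) {
    k <- length(idx)
    0.5 * (k * log(2 * pi * exp(1)) +
             as.numeric(determinant(s[idx, idx, drop = FALSE])$modulus))
  }
  expect_equal(gaussian_mi(m, 1:2, 3:4), h(1:2) + h(3:4) - h(1:4),
               tolerance = 1e-10)
})

test_that("estimate_lagged_model enforces its contract", {
  ts <- generate_var(random_var_system(4, 1), 500, seed = 2)
  expect_error(estimate_lagged_model(ts, 1:2, 2:3), "disjoint")
  expect_error(estimate_lagged_model(ts, integer(0), 2), "non-empty")
  expect_error(estimate_lagged_model(ts, 1, 2, lag = 0), "past must precede")
  short <- regional_timeseries(ts$values[1:15, ])
  expect_error(estimate_lagged_model(short, 1, 2), "timepoints")
})

test_that("estimated joint covariance matches the Lyapunov oracle blocks", {
  sys <- random_var_system(4, seed = 11, radius = 0.6)
  # independent oracle: fixed-point Lyapunov iteration
  s <- diag(4)
  for (i in 1:600) s <- sys$coupling %*% s %*% t(sys$coupling) + sys$noise_cov
  cross <- sys$coupling %*% s
  d <- sqrt(diag(s))
  expected <- rbind(cbind(s, t(cross)), cbind(cross, s)) / tcrossprod(rep(d, 2))
  ts <- generate_var(sys, 30000, seed = 12)
  m <- estimate_lagged_model(ts, 1:2, 3:4)
  expect_lt(max(abs(m$joint_cov - expected)), 0.03)
})

test_that("double redundancy is the minimum of the four lagged MIs", {
  m <- analytic_model(two_node_ar(0.35, 0.2, self = 0.25), c(1, 1))
  mis <- c(gaussian_mi(m, 1, 3), gaussian_mi(m, 1, 4),
           gaussian_mi(m, 2, 3), gaussian_mi(m, 2, 4))
  expect_equal(double_redundancy_mmi(m), min(mis), tolerance = 1e-14)
  expect_gte(double_redundancy_mmi(m), 0)
})

test_that("atoms vanish for independent channels and sum to TDMI in general", {
  m0 <- lagged_model_from_cov(diag(4), c(1, 1))
  expect_lt(max(abs(phiid_atoms(m0))), 1e-12)
  for (seed in 1:5) {
    sys <- random_var_system(4, seed)
    m <- analytic_model(sys, c(2, 2))
    at <- phiid_atoms(m)
    expect_equal(sum(at), gaussian_mi(m, 1:4, 5:8), tolerance = 1e-9)
  }
})

test_that("single-part information decomposes into its four atom terms", {
  # I(X_past; X_future) = UnX->UnX + UnX->Red + Red->UnX + Red->Red
  sys <- random_var_system(5, seed = 21)
  m <- analytic_model(sys, c(2, 3))
  at <- phiid_atoms(m)
  ixx <- gaussian_mi(m, 1:2, 6:7)
  expect_equal(at[["rtr"]] + at[["rtx"]] + at[["xtr"]] + at[["xtx"]], ixx,
               tolerance = 1e-9)
  iyy <- gaussian_mi(m, 3:5, 8:10)
  expect_equal(at[["rtr"]] + at[["rty"]] + at[["ytr"]] + at[["yty"]], iyy,
               tolerance = 1e-9)
})

test_that("transfer entropy from atoms equals the direct conditional MI", {
  for (seed in c(2, 7)) {
    sys <- random_var_system(4, seed)
    m <- analytic_model(sys, c(2, 2))
    im <- info_measures(phiid_atoms(m))
    s <- m$joint_cov
    te_direct <- cond_mi_from_cov(s, a = 1:2, b = 7:8, c = 3:4)
    expect_equal(im$te_xy, te_direct, tolerance = 1e-9)
    te_yx_direct <- cond_mi_from_cov(s, a = 3:4, b = 5:6, c = 1:2)
    expect_equal(im$te_yx, te_yx_direct, tolerance = 1e-9)
    expect_equal(im$causal_density, im$te_xy + im$te_yx, tolerance = 1e-12)
  }
})

test_that("whole-minus-sum measure matches its direct definition and the
           revised measure adds back the persistent redundancy", {
  m <- analytic_model(two_node_ar(0.2, 0.8, self = 0.4), c(1, 1))
  at <- phiid_atoms(m)
  im <- info_measures(at)
  phi2008_direct <- gaussian_mi(m, 1:2, 3:4) - gaussian_mi(m, 1, 3) -
    gaussian_mi(m, 2, 4)
  expect_equal(im$phi_2008, phi2008_direct, tolerance = 1e-9)
  expect_equal(im$phi_R, im$phi_2008 + at[["rtr"]], tolerance = 1e-12)
  # redundancy-dominated: original measure negative, revised nonnegative
  expect_lt(im$phi_2008, 0)
  expect_gte(im$phi_R, -1e-9)
})

test_that("MMI leaves one part with zero unique information per target", {
  # single-target unique information is a down-set difference of atoms:
  # Un(Xp -> Xf) = xtr + xtx, Un(Yp -> Xf) = ytr + ytx, and so on; under
  # MMI one of the two sources always has zero unique information
  for (seed in c(33, 47)) {
    sys <- random_var_system(4, seed)
    m <- analytic_model(sys, c(2, 2))
    at <- phiid_atoms(m)
    un <- function(past, targets) sum(unlist(at[paste0(past, "t", targets)]))
    expect_lt(min(abs(un("x", c("r", "x"))), abs(un("y", c("r", "x")))), 1e-9)
    expect_lt(min(abs(un("x", c("r", "y"))), abs(un("y", c("r", "y")))), 1e-9)
    expect_lt(min(abs(un("x", c("r", "x", "y", "s"))),
                  abs(un("y", c("r", "x", "y", "s")))), 1e-9)
  }
})

test_that("phi_R is symmetric under exchange of the parts", {
  ts <- generate_var(random_var_system(4, 3), 800, seed = 4)
  a <- phi_measures(ts, 1:2, 3:4)
  b <- phi_measures(ts, 3:4, 1:2)
  expect_equal(a$phi_R, b$phi_R, tolerance = 1e-10)
  expect_equal(a$te_xy, b$te_yx, tolerance = 1e-10)
})

test_that("pairwise matrix reduces correctly and respects block structure", {
  ts2 <- two_node_ar(0.3, 0, n_time = 600, seed = 5)
  pm <- pairwise_matrix(ts2, measure = "phi_R")
  expect_equal(pm$global_mean, pm$matrix[1, 2])
  expect_true(is.nan(pm$matrix[1, 1]))
  # two independent strongly coupled blocks
  a_block <- matrix(c(0.3, 0.4, 0.4, 0.3), 2, 2)
  a <- rbind(cbind(a_block, matrix(0, 2, 2)), cbind(matrix(0, 2, 2), a_block))
  ts4 <- generate_var(var_system(a), 4000, seed = 6)
  pm4 <- pairwise_matrix(ts4, measure = "phi_R")
  expect_equal(pm4$matrix, t(pm4$matrix))
  within <- c(pm4$matrix[1, 2], pm4$matrix[3, 4])
  between <- c(pm4$matrix[1, 3], pm4$matrix[1, 4], pm4$matrix[2, 3], pm4$matrix[2, 4])
  expect_gt(min(within), max(between))
})

test_that("bipartition sampling at k = 2 over all pairs equals the pairwise mean", {
  ts <- generate_var(random_var_system(4, 8), 900, seed = 9)
  pm <- pairwise_matrix(ts, measure = "phi_R")
  bp <- bipartition_phi(ts, k = 2, n_sets = 300, seed = 10)
  # 300 draws over 6 pairs: close to the pairwise mean, exact under full cover
  expect_equal(bp$mean_phi_R, pm$global_mean, tolerance = 0.05)
  expect_error(bipartition_phi(ts, k = 3, n_sets = 5, seed = 1), "even")
  expect_error(bipartition_phi(ts, k = 2, n_sets = 0, seed = 1), "n_sets")
  expect_identical(bipartition_phi(ts, 2, 20, seed = 3)$values,
                   bipartition_phi(ts, 2, 20, seed = 3)$values)
})

test_that("debiasing removes the estimation floor of finite samples", {
  ts <- generate_var(two_node_ar(0.45, 0), 5000, seed = 13)
  db <- debias(ts, n_surrogates = 5, seed = 14)
  expect_gt(db$debiased[["phi_R"]], 0)
  expect_lt(abs(db$debiased[["phi_R"]] - db$empirical[["phi_R"]]) /
              db$empirical[["phi_R"]], 0.10)
  expect_error(debias(ts, n_surrogates = 0), ">= 1")
  # a surrogate of a surrogate carries no temporal information to debias
  surr <- time_shuffle_surrogate(ts, seed = 15)
  db2 <- debias(surr, n_surrogates = 8, seed = 16)
  expect_lt(abs(db2$debiased[["phi_R"]]), 0.005)
})
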
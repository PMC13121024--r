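test_that("normalized dynamics are stable with the circulant lattice spectrum", {
  zero_cn <- suppressWarnings(connectome(matrix(0, 3, 3)))
  expect_equal(normalize_dynamics(zero_cn), -diag(3), ignore_attr = TRUE)
  cn <- synthetic_connectome(12, 0.3, seed = 1)
  a <- normalize_dynamics(cn)
  expect_lt(max(Re(eigen(a, only.values = TRUE)$values)), 0)
  # ring lattice k = 2, n = 5, unit weights: circulant eigenvalues 2cos(2 pi j / 5)
  ring <- matrix(0, 5, 5)
  for (i in 1:5) for (d in c(-1, 1)) ring[i, ((i - 1 + d) %% 5) + 1] <- 1
  lam <- 2 * cos(2 * pi * (0:4) / 5)
  expected <- sort(lam / (max(lam) + 1) - 1)
  got <- sort(Re(eigen(normalize_dynamics(connectome(ring)), only.values = TRUE)$values))
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("scalar system matches the closed-form Gramian energy", {
  sys <- control_system(matrix(-1), B = 1, T_horizon = 1)
  e <- min_energy(sys, 0, 1)
  w <- (1 - exp(-2)) / 2
  expect_equal(e$total, 1 / w, tolerance = 1e-9)
  expect_equal(sum(e$per_node), e$total, tolerance = 1e-6)
})

test_that("free evolution costs nothing and energies are additive", {
  cn <- synthetic_connectome(6, 0.5, seed = 2)
  sys <- control_system(cn)
  x0 <- rnorm(6)
  e0 <- min_energy(sys, x0, drop(sys$expAT %*% x0))
  expect_lt(abs(e0$total), 1e-9)
  xf <- rnorm(6)
  e <- min_energy(sys, x0, xf)
  expect_gt(e$total, 0)
  expect_equal(sum(e$per_node), e$total, tolerance = 1e-6)
})

test_that("Gramian energies agree with a brute-force discretized control oracle", {
  for (seed in 1:4) {
    n <- 4
    sys_raw <- phidyn:::with_seed(seed, {
      m <- matrix(rnorm(n * n), n, n); m <- (m + t(m)) / 2; abs(m)
    })
    diag(sys_raw) <- 0
    cn <- connectome(sys_raw)
    b <- phidyn:::with_seed(seed + 100, runif(n, 0.3, 1))
    sys <- control_system(cn, B = b)
    x0 <- phidyn:::with_seed(seed + 200, rnorm(n))
    xf <- phidyn:::with_seed(seed + 300, rnorm(n))
    e <- min_energy(sys, x0, xf, per_node = FALSE)
    bf <- brute_force_energy(sys$A, b, 1, x0, xf, n_steps = 400)
    expect_lt(abs(e$total - bf) / e$total, 0.01)
  }
})

test_that("reducing control weights never reduces the transition energy", {
  for (seed in 1:25) {
    n <- 5
    cn <- synthetic_connectome(n, 0.5, seed = seed)
    b1 <- phidyn:::with_seed(seed + 50, runif(n, 0.5, 1))
    b2 <- b1 * phidyn:::with_seed(seed + 70, runif(n, 0.5, 1))
    x0 <- phidyn:::with_seed(seed + 90, rnorm(n))
    xf <- phidyn:::with_seed(seed + 110, rnorm(n))
    a <- normalize_dynamics(cn)
    e1 <- min_energy(control_system(a, B = b1), x0, xf, per_node = FALSE)$total
    e2 <- min_energy(control_system(a, B = b2), x0, xf, per_node = FALSE)$total
    expect_gte(e2, e1 * (1 - 1e-9))
  }
})

test_that("timeseries transition energy averages the frame pairs", {
  cn <- synthetic_connectome(5, 0.5, seed = 3)
  sys <- control_system(cn)
  # time-constant series: frames z-score to the origin, every transition is
  # the same zero-cost x -> x step
  flat <- regional_timeseries(matrix(rep(seq_len(5), each = 4), 4, 5))
  te <- transition_energy_timeseries(flat, sys)
  expect_equal(diff(range(te$energies)), 0)
  expect_equal(te$mean_energy, min_energy(sys, rep(0, 5), rep(0, 5))$total)
  # two frames: mean equals that single transition
  two <- regional_timeseries(matrix(rnorm(10), 2, 5))
  te2 <- transition_energy_timeseries(two, sys)
  expect_equal(te2$mean_energy, te2$energies[1])
  # white-noise frames: mean within 3 se of trace(W^-1 Cov(v))
  nt <- 3000
  wn <- regional_timeseries(matrix(rnorm(nt * 5), nt, 5))
  te3 <- transition_energy_timeseries(wn, sys)
  # v = x_{t+1} - expAT x_t with z-scored unit-variance frames
  cv <- diag(5) + sys$expAT %*% t(sys$expAT)
  expected <- sum(diag(sys$gramian_inv %*% cv))
  se <- sd(te3$energies) / sqrt(nt - 1)
  expect_lt(abs(te3$mean_energy - expected), 3 * se)
})

test_that("map-weighted control obeys the formula, the clipping and the bound", {
  n <- 8
  expect_equal(heterogeneous_control_weights(regional_map(rep(0, n))),
               rep(1, n), ignore_attr = TRUE)
  expect_equal(heterogeneous_control_weights(regional_map(rep(1, n))),
               rep(1e-3, n), ignore_attr = TRUE)
  expect_error(heterogeneous_control_weights(regional_map(rep(1.5, n))),
               "\\[0, 1\\]")
  cn <- synthetic_connectome(n, 0.4, seed = 4)
  map <- sigmoid_normalize(spatial_map(tiny_coords(n, 5), 0.5, seed = 6))
  a <- normalize_dynamics(cn)
  uni <- control_system(a)
  het <- control_system(a, B = heterogeneous_control_weights(map))
  ts <- generate_var(random_var_system(n, 7, radius = 0.5), 60, seed = 8)
  expect_gte(transition_energy_timeseries(ts, het)$mean_energy,
             transition_energy_timeseries(ts, uni)$mean_energy)
})

test_that("a constant map is indistinguishable from its null maps", {
  n <- 12
  cn <- synthetic_connectome(n, 0.4, seed = 9)
  coords <- tiny_coords(n, 10)
  w <- spatial_weight_matrix(coords)
  flat <- regional_map(rep(0.5, n), normalized = TRUE)
  ts <- generate_var(random_var_system(n, 11, radius = 0.5), 60, seed = 12)
  res <- energy_vs_null_maps(ts, cn, flat, w, n_nulls = 10, seed = 13)
  expect_lt(diff(range(c(res$null_energies, res$empirical))), 1e-9)
})
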
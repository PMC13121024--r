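# Mean-field model tests run at desk scale: 25 regions or fewer, short
# durations, integration step 0.2 ms (stability at finer steps is covered by
# the uncoupled-limit test at 0.1 ms).

test_that("simulation is deterministic and finite", {
  cn <- synthetic_connectome(10, 0.4, seed = 1)
  p <- dmf_parameters(10, G = 1.5, duration = 120, tr = 2, dt = 0.2, seed = 5)
  a <- simulate_dmf(cn, p)
  b <- simulate_dmf(cn, p)
  expect_identical(a$values, b$values)
  expect_true(all(is.finite(a$values)))
  expect_equal(nrow(a$values), 60)
  p2 <- p; p2$seed <- 6
  expect_false(identical(a$values, simulate_dmf(cn, p2)$values))
})

test_that("uncoupled regions show no functional connectivity", {
  cn <- synthetic_connectome(10, 0.4, seed = 2)
  p <- dmf_parameters(10, G = 0, duration = 600, tr = 2, dt = 0.1, seed = 7)
  ts <- simulate_dmf(cn, p)
  fc <- cor(ts$values)
  expect_lt(mean(abs(fc[upper.tri(fc)])), 0.1)
})

test_that("raising inhibitory weights lowers excitatory firing", {
  cn <- synthetic_connectome(10, 0.4, seed = 3)
  p <- dmf_parameters(10, G = 1.5, duration = 120, tr = 2, dt = 0.2, seed = 8)
  lo <- simulate_dmf(cn, p)
  p$J <- rep(1.4, 10)
  hi <- simulate_dmf(cn, p)
  expect_lt(mean(attr(hi, "mean_rate_e")), mean(attr(lo, "mean_rate_e")))
})

test_that("parameter containers validate their ranges", {
  expect_error(dmf_parameters(5, G = -1), "G")
  expect_error(dmf_parameters(5, J = 0.5), "0.7")
  expect_error(dmf_parameters(5, exc_input_scale = 0.5), ">= 1")
  expect_error(dmf_parameters(5, duration = 10, tr = 2), "60")
})

test_that("heterogeneous inhibition follows the map formula exactly", {
  p <- dmf_parameters(4, duration = 120, tr = 2)
  map <- regional_map(c(0, 0.5, 1, 0.25), normalized = TRUE)
  p2 <- heterogeneous_inhibition(p, map)
  expect_equal(p2$J, 0.7 * (1 + map$values), ignore_attr = TRUE)
  expect_equal(p2$J[1], 0.7)
  expect_equal(p2$J[3], 1.4)
  expect_identical(p2$exc_input_scale, p$exc_input_scale)
  expect_error(heterogeneous_inhibition(p, regional_map(c(0, 2, 1, 0.5))),
               "normalized")
})

test_that("nodal stimulation edits only the listed nodes", {
  p <- dmf_parameters(6, duration = 120, tr = 2)
  expect_identical(nodal_stimulation(p, integer(0), 3), p)
  p2 <- nodal_stimulation(p, 4, 3)
  expect_equal(p2$exc_input_scale, c(1, 1, 1, 3, 1, 1))
  p3 <- nodal_stimulation(p, c(1, 2), 1)
  expect_equal(p3$exc_input_scale, rep(1, 6))
  expect_error(nodal_stimulation(p, 9, 3), "out of range")
  expect_error(nodal_stimulation(p, 1, 0.5), ">= 1")
})

test_that("FCD separates stationary noise from regime-switching dynamics", {
  # stationary white noise with non-overlapping windows: similarities
  # concentrated near zero (overlapping windows share samples and correlate
  # by construction, so they are not a null reference)
  wn <- regional_timeseries(phidyn:::with_seed(9, matrix(rnorm(600 * 12), 600, 12)))
  f <- compute_fcd(wn, window = 60, step = 60)
  expect_lt(abs(median(f$value_distribution)), 0.15)
  expect_true(isSymmetric(f$fcd_matrix))
  expect_true(all(abs(diag(f$fcd_matrix) - 1) < 1e-12))
  expect_true(all(f$value_distribution >= -1 & f$value_distribution <= 1))
  # two glued regimes with different FC: similarity values split high/low
  mk <- function(r, seed) {
    phidyn:::with_seed(seed, {
      z <- rnorm(150)
      sapply(1:8, function(j) r * z + sqrt(1 - r^2) * rnorm(150))
    })
  }
  glued <- regional_timeseries(rbind(mk(0.9, 10), mk(0.0, 11)))
  f2 <- compute_fcd(glued, window = 50, step = 5)
  within_regime <- f2$value_distribution[f2$value_distribution > 0.5]
  across_regime <- f2$value_distribution[f2$value_distribution < 0.3]
  expect_gt(length(within_regime), 0)
  expect_gt(length(across_regime), 0)
  # single window: empty distribution
  f3 <- compute_fcd(wn, window = 600, step = 10)
  expect_length(f3$value_distribution, 0)
  expect_error(compute_fcd(wn, window = 700), "longer")
})

test_that("coupling fit returns trivial answers in degenerate cases", {
  cn <- synthetic_connectome(8, 0.4, seed = 4)
  p <- dmf_parameters(8, G = 1, duration = 120, tr = 2, dt = 0.2, seed = 12)
  target <- compute_fcd(simulate_dmf(cn, p), 20, 5)
  one <- fit_global_coupling(cn, target, grid = 1.7, p, n_rep = 1, seed = 13)
  expect_equal(one$G, 1.7)
  # identical distributions: KS statistic numerically zero
  d <- suppressWarnings(ks.test(target$value_distribution,
                                target$value_distribution)$statistic)
  expect_lt(d, 1e-12)
  expect_error(fit_global_coupling(cn, target, numeric(0), p), "non-empty")
})
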
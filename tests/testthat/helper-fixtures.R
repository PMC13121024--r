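# Shared fixtures and independent oracles used across the suite. Everything
# is generated in code; no stored data.

# random stationary VAR system with given total dimension
random_var_system <- function(n, seed, radius = 0.7) {
  phidyn:::with_seed(seed, {
    a <- matrix(rnorm(n * n), n, n)
    a <- a * (radius / max(Mod(eigen(a, only.values = TRUE)$values)))
    l <- matrix(rnorm(n * n, sd = 0.5), n, n)
    q <- crossprod(l) + diag(n) * 0.5
    var_system(a, q)
  })
}

# analytic lagged model of a VAR system (closed-form oracle input)
analytic_model <- function(system, dims, lag = 1L) {
  lagged_model_from_cov(var_lagged_cov(system, lag), dims = dims, lag = lag)
}

# Gaussian conditional mutual information I(a; b | c) straight from a
# covariance matrix -- independent of the package's MI code path
cond_mi_from_cov <- function(s, a, b, c) {
  ld <- function(idx) {
    as.numeric(determinant(s[idx, idx, drop = FALSE], logarithm = TRUE)$modulus)
  }
  0.5 * (ld(c(a, c)) + ld(c(b, c)) - ld(c) - ld(c(a, b, c)))
}

mi_from_cov <- function(s, a, b) {
  ld <- function(idx) {
    as.numeric(determinant(s[idx, idx, drop = FALSE], logarithm = TRUE)$modulus)
  }
  0.5 * (ld(a) + ld(b) - ld(c(a, b)))
}

# brute-force minimum control energy: exact zero-order-hold discretization,
# min-norm least squares over the input sequence
brute_force_energy <- function(a, b_diag, T_horizon, x0, xf, n_steps = 400L) {
  n <- nrow(a)
  dt <- T_horizon / n_steps
  ad <- as.matrix(Matrix::expm(a * dt))
  # integral of e^{As} ds over one step, via augmented exponential
  aug <- rbind(cbind(a, diag(n)), matrix(0, n, 2 * n))
  intg <- as.matrix(Matrix::expm(aug * dt))[1:n, (n + 1):(2 * n)]
  bd <- intg %*% diag(b_diag, n)
  # v = xf - Ad^K x0 = sum_k Ad^{K-1-k} Bd u_k
  g <- matrix(0, n, n * n_steps)
  pow <- diag(n)
  for (k in n_steps:1) {      # columns for u_{k-1}: Ad^{n_steps-k}
    g[, ((k - 1) * n + 1):(k * n)] <- pow %*% bd
    pow <- pow %*% ad
  }
  adk <- diag(n)
  for (i in seq_len(n_steps)) adk <- adk %*% ad
  v <- xf - drop(adk %*% x0)
  u <- drop(t(g) %*% solve(g %*% t(g), v))
  sum(u^2) * dt
}

# independent all-subsets dominance oracle (direct translation of the
# definition; no shared code with the package implementation)
dominance_oracle <- function(x, y) {
  p <- ncol(x)
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    summary(lm(y ~ x[, cols, drop = FALSE]))$r.squared
  }
  vapply(seq_len(p), function(j) {
    others <- setdiff(seq_len(p), j)
    incs_by_size <- vapply(0:(p - 1), function(k) {
      subs <- if (k == 0) list(integer(0)) else
        utils::combn(others, k, simplify = FALSE)
      mean(vapply(subs, function(s) r2(c(s, j)) - r2(s), 0))
    }, 0)
    mean(incs_by_size)
  }, 0)
}

tiny_coords <- function(n, seed = 1) {
  phidyn:::with_seed(seed, matrix(runif(n * 3), n, 3))
}
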
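#' Stationary lag-1 vector-autoregressive system
#'
#' Defines `x_t = A x_{t-1} + e_t` with `e_t ~ N(0, Q)`. The coupling matrix
#' must have spectral radius below 1 (stationarity) and the innovation
#' covariance must be symmetric positive semi-definite.
#'
#' @param coupling N x N lag-1 autoregressive weight matrix.
#' @param noise_cov N x N innovation covariance (defaults to identity).
#' @param labels Region identifiers.
#' @return Object of class `var_system`.
#' @export
var_system <- function(coupling, noise_cov = NULL, labels = NULL) {
  coupling <- as.matrix(coupling)
  if (!is_square_matrix(coupling)) stop("coupling must be square")
  n <- nrow(coupling)
  if (is.null(noise_cov)) noise_cov <- diag(n)
  noise_cov <- as.matrix(noise_cov)
  stop_if_not_symmetric(noise_cov, what = "noise_cov")
  ev <- eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("noise_cov must be positive semi-definite")
  }
  rho <- spectral_radius(coupling)
  if (rho >= 1) {
    stop(sprintf("coupling is non-stationary: spectral radius %.4f >= 1", rho))
  }
  if (is.null(labels)) labels <- default_labels(n)
  structure(list(coupling = coupling, noise_cov = noise_cov,
                 labels = as.character(labels)),
            class = "var_system")
}

#' Stationary covariance of a VAR(1) system
#'
#' Solves the discrete Lyapunov equation `S = A S A' + Q` by Kronecker
#' vectorization; exact for stationary systems.
#'
#' @param system A `var_system`.
#' @return The N x N stationary covariance matrix.
#' @export
var_stationary_cov <- function(system) {
  stopifnot(inherits(system, "var_system"))
  a <- system$coupling
  n <- nrow(a)
  s <- solve(diag(n * n) - kronecker(a, a), as.vector(system$noise_cov))
  s <- matrix(s, n, n)
  (s + t(s)) / 2
}

#' Analytic joint lagged covariance of a VAR(1) system
#'
#' Returns the covariance of the stacked vector `(x_{t-lag}, x_t)`:
#' `[[S, S A'^lag], [A^lag S, S]]` with `S` the stationary covariance.
#' Useful as a closed-form oracle for information measures.
#'
#' @param system A `var_system`.
#' @param lag Positive integer lag in samples.
#' @return A `2N x 2N` covariance matrix (past block first).
#' @export
var_lagged_cov <- function(system, lag = 1L) {
  stopifnot(inherits(system, "var_system"), lag >= 1)
  s <- var_stationary_cov(system)
  a_lag <- diag(nrow(s))
  for (i in seq_len(lag)) a_lag <- system$coupling %*% a_lag
  cross <- a_lag %*% s            # cov(x_t, x_{t-lag})
  rbind(cbind(s, t(cross)), cbind(cross, s))
}

#' Simulate a VAR(1) timeseries
#'
#' Draws Gaussian innovations and iterates `x_t = A x_{t-1} + e_t`, discarding
#' a burn-in (at least 100 steps) so samples come from the stationary
#' distribution. Deterministic given the seed.
#'
#' @param system A `var_system`.
#' @param n_time Number of retained timepoints (>= 10).
#' @param seed Integer seed.
#' @param burn_in Burn-in steps to discard (minimum enforced at 100).
#' @param tr Sampling interval attached to the output.
#' @return A `regional_timeseries`.
#' @export
generate_var <- function(system, n_time, seed, burn_in = 100L, tr = 1) {
  stopifnot(inherits(system, "var_system"))
  if (n_time < 10) stop("n_time must be at least 10")
  burn_in <- max(100L, as.integer(burn_in))
  n <- nrow(system$coupling)
  # innovation factor: eigen square root handles semi-definite Q
  ed <- eigen(system$noise_cov, symmetric = TRUE)
  ed$values[ed$values < 0] <- 0
  l <- ed$vectors %*% diag(sqrt(ed$values), n)
  total <- n_time + burn_in
  x <- with_seed(seed, {
    eps <- matrix(rnorm(total * n), total, n) %*% t(l)
    out <- matrix(0, total, n)
    state <- numeric(n)
    a_t <- t(system$coupling)
    for (t in seq_len(total)) {
      state <- drop(state %*% a_t) + eps[t, ]
      out[t, ] <- state
    }
    out
  })
  regional_timeseries(x[(burn_in + 1):total, , drop = FALSE],
                      labels = system$labels, tr = tr)
}

#' Two-node coupled autoregressive process
#'
#' Convenience constructor for the canonical 2-node system with symmetric
#' cross-coupling `a` and innovation correlation `c`: as `c` grows the system
#' is flooded by common noise (redundancy-dominated); as `a` grows each node
#' influences the other more strongly and synergy rises.
#'
#' @param a Cross-coupling weight, `|a| < 1` (and spectral radius < 1).
#' @param c Innovation correlation, `|c| <= 1`.
#' @param n_time Retained timepoints; if `NULL`, only the system is returned.
#' @param seed Integer seed (required when simulating).
#' @param self Self-coupling weight on the diagonal (default 0).
#' @return A `regional_timeseries` (or the underlying `var_system` when
#'   `n_time` is `NULL`).
#' @export
two_node_ar <- function(a, c, n_time = NULL, seed = NULL, self = 0) {
  if (abs(a) >= 1) stop("|a| must be < 1")
  if (abs(c) > 1) stop("|c| must be <= 1")
  coupling <- matrix(c(self, a, a, self), 2, 2)
  noise <- matrix(c(1, c, c, 1), 2, 2)
  sys <- var_system(coupling, noise, labels = c("X", "Y"))
  if (is.null(n_time)) return(sys)
  if (is.null(seed)) stop("seed is required to simulate")
  generate_var(sys, n_time, seed)
}
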
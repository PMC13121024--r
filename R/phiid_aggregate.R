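measure_names <- function() {
  c("tdmi", "phi_R", "phi_2008", "double_redundancy",
    "causal_density", "net_flow", "te_xy", "te_yx")
}

#' Pairwise information-measure matrix
#'
#' Computes a chosen information-dynamic measure for every unordered region
#' pair and returns the symmetrized matrix together with the global mean over
#' the `N(N-1)/2` unordered pairs. Pairs whose estimation fails are recorded
#' as missing and excluded from the mean (their count is reported).
#'
#' @param ts A `regional_timeseries` with at least two regions.
#' @param lag Lag in samples.
#' @param measure One of `"phi_R"`, `"phi_2008"`, `"tdmi"`,
#'   `"double_redundancy"`, `"causal_density"`, `"net_flow"`, `"te_xy"`,
#'   `"te_yx"`.
#' @return List with `matrix` (N x N, `NaN` diagonal), `global_mean`,
#'   `measure` and `n_failed`.
#' @export
pairwise_matrix <- function(ts, lag = 1L, measure = "phi_R") {
  stopifnot(inherits(ts, "regional_timeseries"))
  measure <- match.arg(measure, measure_names())
  n <- n_regions(ts)
  if (n < 2) stop("need at least two regions")
  m <- matrix(NA_real_, n, n, dimnames = list(ts$labels, ts$labels))
  diag(m) <- NaN
  failed <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      val <- tryCatch(phi_measures(ts, i, j, lag)[[measure]],
                      error = function(e) NA_real_)
      if (is.na(val)) failed <- failed + 1L
      m[i, j] <- m[j, i] <- val
    }
  }
  vals <- m[upper.tri(m)]
  if (failed > 0) {
    message(failed, " of ", n * (n - 1) / 2, " pairs failed estimation; excluded from mean")
  }
  list(matrix = m, global_mean = mean(vals, na.rm = TRUE),
       measure = measure, n_failed = failed)
}

# all measures' pairwise global means in one pass (single model fit per pair)
pairwise_means_all <- function(ts, lag = 1L) {
  n <- n_regions(ts)
  acc <- matrix(NA_real_, n * (n - 1) / 2, length(measure_names()),
                dimnames = list(NULL, measure_names()))
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- k + 1L
      vals <- tryCatch(unlist(phi_measures(ts, i, j, lag)),
                       error = function(e) NULL)
      if (!is.null(vals)) acc[k, ] <- vals[measure_names()]
    }
  }
  colMeans(acc, na.rm = TRUE)
}

#' Mean integrated information over sampled bipartitions
#'
#' Samples `n_sets` region sets of even size `k`, draws a random even
#' bipartition of each, and computes revised integrated information between
#' the two multivariate halves with the same atom machinery used for pairs.
#' With `k = 2` and all pairs sampled this reduces to the pairwise global
#' mean. Deterministic given the seed.
#'
#' @param ts A `regional_timeseries` with at least `k` regions.
#' @param k Even set size (for example 6, split into two groups of 3).
#' @param n_sets Number of sampled sets (>= 1).
#' @param lag Lag in samples.
#' @param seed Integer seed.
#' @return List with `mean_phi_R`, the per-set values and the sampled sets.
#' @export
bipartition_phi <- function(ts, k = 6L, n_sets = 100L, lag = 1L, seed = 1L) {
  stopifnot(inherits(ts, "regional_timeseries"))
  k <- as.integer(k)
  if (k %% 2L != 0L) stop("k must be even")
  if (n_regions(ts) < k) stop("need at least k regions")
  if (n_sets < 1) stop("n_sets must be >= 1")
  n <- n_regions(ts)
  res <- with_seed(seed, {
    sets <- replicate(n_sets, sort(sample.int(n, k)), simplify = FALSE)
    halves <- lapply(sets, function(s) sample(s))  # random even bipartition
    vals <- vapply(halves, function(h) {
      p1 <- h[seq_len(k / 2)]
      p2 <- h[(k / 2 + 1):k]
      tryCatch(phi_measures(ts, p1, p2, lag)$phi_R, error = function(e) NA_real_)
    }, 0)
    list(sets = sets, values = vals)
  })
  list(mean_phi_R = mean(res$values, na.rm = TRUE),
       values = res$values, sets = res$sets, k = k, lag = lag, seed = seed)
}

#' Surrogate-debiased information measures
#'
#' Computes all pairwise global-mean information measures on the empirical
#' timeseries and subtracts the mean of the same quantities over
#' `n_surrogates` jointly time-shuffled surrogates, which preserve each
#' region's marginal distribution and the zero-lag covariance while
#' destroying temporal order.
#'
#' @param ts A `regional_timeseries`.
#' @param lag Lag in samples.
#' @param n_surrogates Number of surrogates (>= 1).
#' @param seed Integer seed.
#' @return List with `debiased`, `empirical` and `surrogate_mean` named
#'   vectors over all measures.
#' @export
debias <- function(ts, lag = 1L, n_surrogates = 10L, seed = 1L) {
  stopifnot(inherits(ts, "regional_timeseries"))
  if (n_surrogates < 1) stop("n_surrogates must be >= 1")
  emp <- pairwise_means_all(ts, lag)
  surr <- vapply(seq_len(n_surrogates), function(i) {
    s <- time_shuffle_surrogate(ts, seed = child_seed(seed, i))
    pairwise_means_all(s, lag)
  }, emp)
  surr_mean <- if (is.matrix(surr)) rowMeans(surr) else surr
  list(debiased = emp - surr_mean, empirical = emp, surrogate_mean = surr_mean,
       n_surrogates = n_surrogates, lag = lag, seed = seed)
}
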
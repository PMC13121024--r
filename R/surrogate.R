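#' Jointly time-shuffled surrogate timeseries
#'
#' Applies one random permutation of time indices jointly to all regions.
#' Each region's marginal distribution and the zero-lag covariance matrix
#' are preserved exactly (rows co-occur unchanged) while all temporal
#' ordering, and hence all lagged structure, is destroyed. Used to debias
#' information estimates.
#'
#' @param ts A `regional_timeseries` with at least 10 timepoints.
#' @param seed Integer seed.
#' @return A `regional_timeseries` of the same shape.
#' @export
time_shuffle_surrogate <- function(ts, seed = 1L) {
  stopifnot(inherits(ts, "regional_timeseries"))
  nt <- n_timepoints(ts)
  if (nt < 10) stop("need at least 10 timepoints")
  perm <- with_seed(seed, sample.int(nt))
  regional_timeseries(ts$values[perm, , drop = FALSE],
                      labels = ts$labels, tr = ts$tr)
}
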
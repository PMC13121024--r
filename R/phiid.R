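# Gaussian integrated information decomposition (MMI redundancy).
#
# The decomposition works on a lagged Gaussian model of two (possibly
# multivariate) parts X and Y: the joint covariance of the stacked vector
# (X_past, Y_past, X_future, Y_future). All information quantities are in
# nats and follow from log-determinants of sub-covariances.

PHIID_NODES <- c("r", "x", "y", "s")

# collections of constituent sources per lattice node: 1 = part X, 2 = part Y
phiid_collections <- list(
  r = list(1L, 2L),
  x = list(1L),
  y = list(2L),
  s = list(c(1L, 2L))
)

# single-lattice partial order: r <= {x, y} <= s, x and y incomparable
phiid_leq_single <- matrix(
  c(1, 1, 1, 1,   # r <= r,x,y,s
    0, 1, 0, 1,   # x <= x,s
    0, 0, 1, 1,   # y <= y,s
    0, 0, 0, 1),  # s <= s
  nrow = 4, byrow = TRUE, dimnames = list(PHIID_NODES, PHIID_NODES)
)

phiid_atom_names <- function() {
  as.vector(t(outer(PHIID_NODES, PHIID_NODES,
                    function(p, f) paste0(p, "t", f))))
}

# 16 x 16 zeta (down-set indicator) matrix of the product partial order;
# row k gives the atoms in the down-set of node pair k. Fixed and invertible.
phiid_zeta <- function() {
  pairs <- expand.grid(fut = PHIID_NODES, past = PHIID_NODES,
                       stringsAsFactors = FALSE)[, c("past", "fut")]
  z <- matrix(0L, 16L, 16L)
  for (k in seq_len(16L)) {
    for (l in seq_len(16L)) {
      z[k, l] <- phiid_leq_single[pairs$past[l], pairs$past[k]] *
        phiid_leq_single[pairs$fut[l], pairs$fut[k]]
    }
  }
  nm <- paste0(pairs$past, "t", pairs$fut)
  dimnames(z) <- list(nm, nm)
  z
}

#' Lagged Gaussian model of a bipartite system
#'
#' Estimates the joint covariance of `(X_{t-lag}, Y_{t-lag}, X_t, Y_t)` from a
#' regional timeseries, after z-scoring every region. This is the sufficient
#' statistic for all Gaussian information measures in the package.
#'
#' @param ts A `regional_timeseries`.
#' @param part1,part2 Disjoint, non-empty region index (or label) sets.
#' @param lag Positive lag in samples (the past must precede the future).
#' @return Object of class `lagged_gaussian_model` with `joint_cov`, `dims`
#'   (sizes of the two parts) and `lag`.
#' @export
estimate_lagged_model <- function(ts, part1, part2, lag = 1L) {
  stopifnot(inherits(ts, "regional_timeseries"))
  if (is.character(part1)) part1 <- match(part1, ts$labels)
  if (is.character(part2)) part2 <- match(part2, ts$labels)
  part1 <- as.integer(part1); part2 <- as.integer(part2)
  if (anyNA(part1) || anyNA(part2)) stop("unknown region labels")
  if (length(part1) < 1 || length(part2) < 1) stop("parts must be non-empty")
  if (length(intersect(part1, part2)) > 0) stop("parts must be disjoint")
  if (any(c(part1, part2) < 1) || any(c(part1, part2) > n_regions(ts))) {
    stop("part indices out of range")
  }
  lag <- as.integer(lag)
  if (lag < 1) stop("lag must be >= 1: the past must precede the future")
  d <- length(part1) + length(part2)
  nt <- n_timepoints(ts)
  if (nt - lag < 10 * d) {
    stop("need at least ", 10 * d + lag, " timepoints for ", d, " regions at lag ", lag)
  }
  z <- zscore_cols(ts$values[, c(part1, part2), drop = FALSE])
  past <- z[seq_len(nt - lag), , drop = FALSE]
  fut <- z[(lag + 1):nt, , drop = FALSE]
  jc <- cov(cbind(past, fut))
  lagged_model_from_cov(jc, dims = c(length(part1), length(part2)), lag = lag)
}

#' Lagged Gaussian model from a known joint covariance
#'
#' Builds the model directly from a `2(p1+p2)` joint covariance over
#' `(X_past, Y_past, X_future, Y_future)`, for instance the analytic lagged
#' covariance of a VAR system. The covariance is scaled to unit variances
#' (the analogue of z-scoring; mutual information is unaffected) and
#' diagonally loaded if near-singular.
#'
#' @param joint_cov Symmetric covariance matrix of the stacked vector.
#' @param dims Integer vector `c(p1, p2)` of part sizes.
#' @param lag Lag in samples (metadata).
#' @param epsilon Relative diagonal loading applied when the smallest
#'   eigenvalue falls below 1e-10.
#' @return A `lagged_gaussian_model`.
#' @export
lagged_model_from_cov <- function(joint_cov, dims, lag = 1L, epsilon = 1e-9) {
  joint_cov <- as.matrix(joint_cov)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 2L, all(dims >= 1L))
  d <- sum(dims)
  if (!is_square_matrix(joint_cov) || nrow(joint_cov) != 2L * d) {
    stop("joint_cov must be ", 2L * d, " x ", 2L * d)
  }
  stop_if_not_symmetric(joint_cov, tol = 1e-6, what = "joint_cov")
  joint_cov <- (joint_cov + t(joint_cov)) / 2
  sds <- sqrt(diag(joint_cov))
  if (any(sds <= 0)) stop("joint_cov has non-positive variances")
  joint_cov <- joint_cov / tcrossprod(sds)
  ev <- eigen(joint_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    joint_cov <- joint_cov + diag(epsilon * mean(diag(joint_cov)), 2L * d)
    ev <- eigen(joint_cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-12) {
      stop(sprintf(
        "joint covariance is rank deficient after diagonal loading (min eigenvalue %.3g, condition %.3g)",
        min(ev), max(ev) / max(min(ev), .Machine$double.xmin)))
    }
  }
  structure(list(joint_cov = joint_cov, dims = dims, lag = as.integer(lag)),
            class = "lagged_gaussian_model")
}

# stacked indices of a block: part in {1, 2}, time in {"past", "future"}
model_block_idx <- function(model, part, time) {
  p1 <- model$dims[1]; p2 <- model$dims[2]
  offs <- if (time == "past") 0L else p1 + p2
  if (part == 1L) offs + seq_len(p1) else offs + p1 + seq_len(p2)
}

# indices for a collection of sources (vector subset of {1,2}) at a time slice
collection_idx <- function(model, sources, time) {
  unlist(lapply(as.integer(sources), function(p) model_block_idx(model, p, time)))
}

#' Gaussian mutual information between two index sets
#'
#' `I = (log det S_a + log det S_b - log det S_ab) / 2` in nats, over
#' disjoint index sets of the stacked `(past, future)` vector.
#'
#' @param model A `lagged_gaussian_model`.
#' @param set_a,set_b Disjoint stacked-index sets.
#' @return Mutual information in nats.
#' @export
gaussian_mi <- function(model, set_a, set_b) {
  stopifnot(inherits(model, "lagged_gaussian_model"))
  set_a <- as.integer(set_a); set_b <- as.integer(set_b)
  d2 <- nrow(model$joint_cov)
  if (any(c(set_a, set_b) < 1) || any(c(set_a, set_b) > d2)) {
    stop("index sets out of range")
  }
  if (length(intersect(set_a, set_b)) > 0) stop("index sets must be disjoint")
  s <- model$joint_cov
  mi <- 0.5 * (logdet_spd(s[set_a, set_a, drop = FALSE]) +
                 logdet_spd(s[set_b, set_b, drop = FALSE]) -
                 logdet_spd(s[c(set_a, set_b), c(set_a, set_b), drop = FALSE]))
  # numerical floor: exact-independence cases may come out at -1e-16
  if (mi < 0 && mi > -1e-12) mi <- 0
  mi
}

# MI between a past collection and a future collection of sources
collection_mi <- function(model, past_sources, fut_sources) {
  gaussian_mi(model,
              collection_idx(model, past_sources, "past"),
              collection_idx(model, fut_sources, "future"))
}

# MMI double-redundancy function at a product-lattice node pair:
# min over MIs between every constituent past collection and every
# constituent future collection.
redundancy_at <- function(model, past_node, fut_node) {
  pcols <- phiid_collections[[past_node]]
  fcols <- phiid_collections[[fut_node]]
  vals <- vapply(pcols, function(a) {
    vapply(fcols, function(b) collection_mi(model, a, b), 0)
  }, numeric(length(fcols)))
  min(vals)
}

#' MMI double redundancy
#'
#' Minimum of the four lagged mutual informations between the (possibly
#' multivariate) parts: `min{I(Xp;Xf), I(Xp;Yf), I(Yp;Xf), I(Yp;Yf)}`. This
#' is the bottom node of the product lattice and is always nonnegative.
#'
#' @param model A `lagged_gaussian_model`.
#' @return Double redundancy in nats.
#' @export
double_redundancy_mmi <- function(model) {
  stopifnot(inherits(model, "lagged_gaussian_model"))
  redundancy_at(model, "r", "r")
}

#' The 16 information atoms of a bipartite dynamical system
#'
#' Computes the minimum-mutual-information double-redundancy function at all
#' 16 product-lattice node pairs over `{Red, UnX, UnY, Syn}` past and future,
#' then solves the (fixed, triangular) zeta system of the product partial
#' order for the atoms. Atoms may legitimately be negative and are never
#' clipped. The atoms sum to the time-delayed mutual information.
#'
#' @param model A `lagged_gaussian_model`.
#' @return Object of class `phiid_atoms`: a named numeric vector of the 16
#'   atoms (`rtr`, `rtx`, ..., `sts`; past node, then future node), with the
#'   model attached as an attribute.
#' @export
phiid_atoms <- function(model) {
  stopifnot(inherits(model, "lagged_gaussian_model"))
  nodes <- PHIID_NODES
  red <- numeric(16L)
  nm <- character(16L)
  k <- 0L
  for (p in nodes) {
    for (f in nodes) {
      k <- k + 1L
      red[k] <- redundancy_at(model, p, f)
      nm[k] <- paste0(p, "t", f)
    }
  }
  names(red) <- nm
  z <- phiid_zeta()
  atoms <- solve(z, red[rownames(z)])
  atoms <- atoms[phiid_atom_names()]
  structure(atoms, class = "phiid_atoms", model = model,
            redundancies = red)
}

#' @export
print.phiid_atoms <- function(x, ...) {
  cat("<phiid_atoms> (nats)\n")
  m <- matrix(unclass(x), 4, 4, byrow = TRUE,
              dimnames = list(paste0(PHIID_NODES, "_past"),
                              paste0(PHIID_NODES, "_future")))
  print(round(m, 6))
  invisible(x)
}

#' Derived information-dynamic measures
#'
#' Aggregates the 16 atoms into the package's summary measures: time-delayed
#' mutual information (atom sum), revised integrated information `phi_R`
#' (all nine synergy-containing atoms plus the two pure-transfer atoms),
#' whole-minus-sum integrated information `phi_2008 = phi_R - RedRed`,
#' directed transfer entropies and causal density, and the net (absolute)
#' pure-transfer imbalance.
#'
#' @param atoms A `phiid_atoms` vector.
#' @param model Optional `lagged_gaussian_model` the atoms came from
#'   (defaults to the one attached to `atoms`).
#' @return Object of class `info_measures`: named list with `tdmi`, `phi_R`,
#'   `phi_2008`, `double_redundancy`, `causal_density`, `net_flow`, `te_xy`,
#'   `te_yx`, all in nats.
#' @export
info_measures <- function(atoms, model = attr(atoms, "model")) {
  stopifnot(inherits(atoms, "phiid_atoms"))
  a <- unclass(atoms)
  phi_r <- a[["sts"]] + a[["stx"]] + a[["sty"]] + a[["str"]] +
    a[["rts"]] + a[["xts"]] + a[["yts"]] +
    a[["xty"]] + a[["ytx"]]
  te_xy <- a[["str"]] + a[["sty"]] + a[["xtr"]] + a[["xty"]]
  te_yx <- a[["str"]] + a[["stx"]] + a[["ytr"]] + a[["ytx"]]
  out <- list(
    tdmi = sum(a),
    phi_R = phi_r,
    phi_2008 = phi_r - a[["rtr"]],
    double_redundancy = a[["rtr"]],
    causal_density = te_xy + te_yx,
    net_flow = abs(a[["xty"]] - a[["ytx"]]),
    te_xy = te_xy,
    te_yx = te_yx
  )
  structure(out, class = "info_measures")
}

#' @export
print.info_measures <- function(x, ...) {
  cat("<info_measures> (nats)\n")
  v <- unlist(x)
  print(round(v, 6))
  invisible(x)
}

#' Information measures between two parts of a timeseries
#'
#' Convenience wrapper: estimates the lagged Gaussian model, the 16 atoms and
#' the derived measures in one call.
#'
#' @inheritParams estimate_lagged_model
#' @return An `info_measures` list.
#' @export
phi_measures <- function(ts, part1, part2, lag = 1L) {
  info_measures(phiid_atoms(estimate_lagged_model(ts, part1, part2, lag)))
}
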
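# Spatially autocorrelated regional maps, spatial weights, Moran's I and
# Moran spectral randomization surrogates.

#' Spatial weight matrix from coordinates
#'
#' Inverse Euclidean distance weights with zero diagonal, optionally
#' row-normalized (the package default convention for spatial analyses).
#'
#' @param coords N x 3 matrix of positions.
#' @param row_normalize Divide each row by its sum (default `TRUE`).
#' @return N x N nonnegative weight matrix with zero diagonal.
#' @export
spatial_weight_matrix <- function(coords, row_normalize = TRUE) {
  coords <- as.matrix(coords)
  d <- as.matrix(dist(coords))
  if (any(d[upper.tri(d)] == 0)) {
    stop("coincident coordinates: inverse-distance weights undefined")
  }
  w <- 1 / d
  diag(w) <- 0
  if (row_normalize) w <- w / rowSums(w)
  w
}

#' Moran's I spatial autocorrelation
#'
#' `I = (N / sum(W)) * (z' W z) / (z' z)` with `z` the centred values.
#'
#' @param values Numeric vector (a `regional_map` is accepted).
#' @param weights N x N spatial weight matrix, zero diagonal.
#' @return Moran's I (NA for constant input).
#' @export
moran_i <- function(values, weights) {
  if (inherits(values, "regional_map")) values <- values$values
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) return(NA_real_)
  n <- length(z)
  (n / sum(weights)) * drop(z %*% weights %*% z) / denom
}

#' Spatially autocorrelated Gaussian random field map
#'
#' Samples a Gaussian random field over the supplied coordinates with a
#' squared-exponential covariance `exp(-d^2 / (2 l^2))`; larger correlation
#' lengths give smoother maps (higher Moran's I). Returned raw
#' (unnormalized); pass through [sigmoid_normalize()] for `[0, 1]` maps.
#'
#' @param coords N x 3 matrix of positions (N >= 4, not all identical).
#' @param corr_length Positive correlation length on the coordinate scale.
#' @param seed Integer seed.
#' @return A raw `regional_map`.
#' @export
spatial_map <- function(coords, corr_length, seed = 1L) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4) stop("need at least 4 regions")
  if (max(dist(coords)) == 0) stop("degenerate coordinates: all positions identical")
  if (corr_length <= 0) stop("corr_length must be positive")
  d <- as.matrix(dist(coords))
  k <- exp(-d^2 / (2 * corr_length^2))
  ed <- eigen(k, symmetric = TRUE)
  ed$values[ed$values < 1e-12] <- 0
  l <- ed$vectors %*% diag(sqrt(ed$values), nrow(k))
  vals <- with_seed(seed, drop(l %*% rnorm(nrow(k))))
  regional_map(vals)
}

# eigenvalue blocks: consecutive (sorted) eigenvalues within a relative
# tolerance of the block opener are interchangeable
msr_blocks <- function(lambda, block_tol) {
  scale <- max(abs(lambda), .Machine$double.eps)
  blocks <- integer(length(lambda))
  b <- 1L
  blocks[1] <- b
  for (i in seq_along(lambda)[-1]) {
    opener <- lambda[match(b, blocks)]
    if (abs(lambda[i] - opener) > block_tol * max(abs(opener), 0.01 * scale)) {
      b <- b + 1L
    }
    blocks[i] <- b
  }
  blocks
}

#' Moran spectral randomization surrogate maps
#'
#' Projects the map onto the eigenvectors of the doubly centred spatial
#' weight matrix, randomizes coefficient signs and permutes coefficients
#' within blocks of similar eigenvalue, then restores the input mean
#' exactly. Surrogates preserve the map's mean (to 1e-9) and approximately
#' its Moran's I, providing spatial-autocorrelation-preserving nulls.
#'
#' @param map A `regional_map` (or numeric vector).
#' @param weights Symmetric part is used; nonnegative, zero diagonal.
#' @param n_surr Number of surrogates (>= 1).
#' @param seed Integer seed.
#' @param block_tol Relative eigenvalue tolerance grouping interchangeable
#'   eigenvectors (default 0.05).
#' @return List of `regional_map` surrogates.
#' @export
msr_surrogate_maps <- function(map, weights, n_surr = 99L, seed = 1L,
                               block_tol = 0.05) {
  if (!inherits(map, "regional_map")) map <- regional_map(map)
  if (n_surr < 1) stop("n_surr must be >= 1")
  x <- map$values
  n <- length(x)
  if (sd(x) == 0) {
    return(replicate(n_surr, map, simplify = FALSE))
  }
  w <- as.matrix(weights)
  if (!is_square_matrix(w) || nrow(w) != n) stop("weights must be N x N")
  w <- (w + t(w)) / 2
  diag(w) <- 0
  cmat <- diag(n) - matrix(1 / n, n, n)
  h <- cmat %*% w %*% cmat
  ed <- eigen((h + t(h)) / 2, symmetric = TRUE)
  v <- ed$vectors
  blocks <- msr_blocks(ed$values, block_tol)
  xc <- x - mean(x)
  coefs <- drop(crossprod(v, xc))
  with_seed(seed, {
    lapply(seq_len(n_surr), function(i) {
      cs <- coefs
      for (b in unique(blocks)) {
        idx <- which(blocks == b)
        if (length(idx) > 1) cs[idx] <- cs[sample(idx)]
      }
      cs <- cs * sample(c(-1, 1), n, replace = TRUE)
      xs <- drop(v %*% cs)
      xs <- xs - mean(xs) + mean(x)
      regional_map(xs, labels = map$labels)
    })
  })
}
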
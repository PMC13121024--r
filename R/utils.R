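#' @useDynLib phidyn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor cov sd rnorm runif p.adjust ks.test lm lm.fit coef
#'   quantile median var dist t.test setNames
#' @importFrom utils head read.delim write.table combn modifyList
NULL

# Run code with a temporary RNG state seeded at `seed`; restores the caller's
# .Random.seed so generators are pure functions of (parameters, seed).
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream index, staying inside
# 32-bit integer range.
child_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + 7919 * stream) %% 2147483647)
}

# Column-wise z-scoring; constant columns map to zero rather than NaN.
zscore_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  s[s < .Machine$double.eps] <- 1
  sweep(sweep(x, 2L, mu, "-"), 2L, s, "/")
}

# log-determinant of a symmetric positive definite matrix via Cholesky.
logdet_spd <- function(m) {
  m <- as.matrix(m)
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(ch)) {
    stop("matrix is not positive definite (log-determinant undefined)")
  }
  2 * sum(log(diag(ch)))
}

spectral_radius <- function(m) {
  max(Mod(eigen(m, only.values = TRUE)$values))
}

is_square_matrix <- function(m) {
  is.matrix(m) && nrow(m) == ncol(m)
}

stop_if_not_symmetric <- function(m, tol = 1e-8, what = "matrix") {
  if (!is_square_matrix(m)) stop(what, " must be a square matrix")
  if (max(abs(m - t(m))) > tol) {
    stop(what, " must be symmetric (max asymmetry ",
         format(max(abs(m - t(m)))), " > ", tol, ")")
  }
  invisible(TRUE)
}

default_labels <- function(n, prefix = "R") sprintf("%s%03d", prefix, seq_len(n))

mat_expm <- function(m) {
  as.matrix(Matrix::expm(Matrix::Matrix(m)))
}
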
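# Bespoke statistics: dominance analysis with permutation testing, spatially
# constrained correlation, cross-species gene ranking, sigmoid normalization
# and FDR plumbing.

r2_of <- function(x, y) {
  if (is.null(x) || ncol(x) == 0) return(0)
  fit <- lm.fit(cbind(1, x), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Dominance analysis of a multiple regression
#'
#' General dominance: each predictor's importance is its incremental
#' contribution to R-squared when added to a subset of the remaining
#' predictors, averaged first over subsets of equal size and then over
#' sizes. Importances sum exactly to the full-model R-squared, so they
#' partition the variance explained across predictors. Exhaustive subset
#' enumeration (p <= 15 enforced).
#'
#' @param predictors n x p numeric matrix (p >= 2, n > p).
#' @param target Numeric response of length n.
#' @return Object of class `dominance_result`: `importance` (per predictor),
#'   `total_r2`, `adjusted_r2`, `percent_importance` (shares summing to
#'   100).
#' @export
dominance_analysis <- function(predictors, target) {
  x <- as.matrix(predictors)
  y <- as.numeric(target)
  n <- nrow(x); p <- ncol(x)
  if (p < 2) stop("need at least two predictors")
  if (p > 15) stop("exhaustive dominance enumeration limited to p <= 15")
  if (n <= p) stop("need more observations than predictors")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))
  if (qr(cbind(1, scale(x)))$rank < p + 1 ||
      kappa(crossprod(scale(x)), exact = TRUE) > 1e10) {
    stop("predictors are (near-)collinear; dominance analysis undefined")
  }
  # R^2 of every subset, indexed by bitmask
  n_sub <- 2^p
  r2 <- numeric(n_sub)
  for (mask in seq_len(n_sub - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) > 0)
    r2[mask + 1] <- r2_of(x[, idx, drop = FALSE], y)
  }
  imp <- numeric(p)
  for (j in seq_len(p)) {
    bit_j <- bitwShiftL(1L, j - 1L)
    others <- setdiff(seq_len(p), j)
    # mean increment per subset size k = 0..p-1, then mean over sizes
    by_size <- numeric(p)
    counts <- numeric(p)
    masks <- 0L
    all_masks <- 0:(2^(p - 1) - 1)
    for (m in all_masks) {
      # map the (p-1)-bit mask over `others` onto the full bitmask
      full <- 0L
      k <- 0L
      for (oi in seq_along(others)) {
        if (bitwAnd(m, bitwShiftL(1L, oi - 1L)) > 0) {
          full <- bitwOr(full, bitwShiftL(1L, others[oi] - 1L))
          k <- k + 1L
        }
      }
      inc <- r2[bitwOr(full, bit_j) + 1] - r2[full + 1]
      by_size[k + 1] <- by_size[k + 1] + inc
      counts[k + 1] <- counts[k + 1] + 1
    }
    imp[j] <- mean(by_size / counts)
  }
  names(imp) <- colnames(x)
  total <- r2[n_sub]
  adj <- 1 - (1 - total) * (n - 1) / (n - p - 1)
  structure(list(importance = imp, total_r2 = total, adjusted_r2 = adj,
                 percent_importance = 100 * imp / total),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  cat(sprintf("<dominance_result> R2 = %.4f (adjusted %.4f)\n",
              x$total_r2, x$adjusted_r2))
  print(round(x$percent_importance, 1))
  invisible(x)
}

#' Permutation test of the multiple-regression R-squared
#'
#' One-sided test of the full-model R-squared against a null distribution
#' from refitting with randomly permuted target values (predictors fixed):
#' `p = (1 + #{R2_perm >= R2_emp}) / (n_perm + 1)`.
#'
#' @param predictors n x p matrix.
#' @param target Response vector.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return List with `p_value`, `r2` and the null `r2_perm`.
#' @export
permutation_r2_test <- function(predictors, target, n_perm = 999L, seed = 1L) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  x <- as.matrix(predictors)
  y <- as.numeric(target)
  r2_emp <- r2_of(x, y)
  r2_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) r2_of(x, sample(y)), 0)
  })
  p <- (1 + sum(r2_perm >= r2_emp)) / (n_perm + 1)
  list(p_value = p, r2 = r2_emp, r2_perm = r2_perm)
}

#' Spatial correlation against autocorrelation-preserving nulls
#'
#' Spearman correlation between two regional maps, tested against null
#' correlations of `map_b` with Moran-spectral surrogates of `map_a`
#' (preserving the mean and spatial autocorrelation of `map_a`). Two-sided
#' empirical p by absolute value.
#'
#' @param map_a,map_b `regional_map`s (or numeric vectors) of equal length.
#' @param weights Spatial weight matrix.
#' @param n_surr Number of surrogates (>= 99).
#' @param seed Integer seed.
#' @return Object of class `spatial_corr_result`: `rho`, `p_null`,
#'   `null_distribution`.
#' @export
spatial_corr_msr <- function(map_a, map_b, weights, n_surr = 999L, seed = 1L) {
  if (!inherits(map_a, "regional_map")) map_a <- regional_map(map_a)
  if (!inherits(map_b, "regional_map")) map_b <- regional_map(map_b)
  a <- map_a$values; b <- map_b$values
  if (length(a) != length(b)) stop("maps must have the same length")
  if (sd(a) == 0 || sd(b) == 0) stop("constant map: rank correlation undefined")
  if (n_surr < 99) stop("n_surr must be >= 99")
  rho <- cor(a, b, method = "spearman")
  surr <- msr_surrogate_maps(map_a, weights, n_surr = n_surr, seed = seed)
  nulls <- vapply(surr, function(s) cor(s$values, b, method = "spearman"), 0)
  p <- (1 + sum(abs(nulls) >= abs(rho))) / (n_surr + 1)
  structure(list(rho = rho, p_null = p, null_distribution = nulls),
            class = "spatial_corr_result")
}

#' @export
print.spatial_corr_result <- function(x, ...) {
  cat(sprintf("<spatial_corr_result> rho = %.3f, p(null) = %.4g (%d surrogates)\n",
              x$rho, x$p_null, length(x$null_distribution)))
  invisible(x)
}

#' Cross-species consistency ranking of genes
#'
#' Within each species, genes are ranked by their signed spatial correlation
#' (most negative first); ranks are averaged across species, the averaged
#' ranks are z-scored, and the final score is the magnitude of that z-score,
#' so genes consistently extreme in either direction score highest.
#'
#' @param per_species_correlations species x genes numeric matrix (all genes
#'   present for every species; no missing entries).
#' @param z_first If `TRUE`, z-score within species before averaging instead
#'   (alternative order of operations).
#' @return Data frame sorted by decreasing `score`, with `gene`,
#'   `mean_rank`, `z` and `score` columns.
#' @export
cross_species_gene_rank <- function(per_species_correlations, z_first = FALSE) {
  m <- as.matrix(per_species_correlations)
  if (anyNA(m)) stop("missing entries: filter to the common gene set first")
  if (is.null(colnames(m))) colnames(m) <- paste0("g", seq_len(ncol(m)))
  ranks <- t(apply(m, 1, rank, ties.method = "average"))  # most negative = 1
  if (ncol(m) == 1) ranks <- matrix(ranks, nrow = nrow(m))
  if (z_first) {
    zr <- t(apply(ranks, 1, function(r) (r - mean(r)) / sd(r)))
    z <- colMeans(zr)
  } else {
    mr <- colMeans(ranks)
    z <- (mr - mean(mr)) / sd(mr)
  }
  out <- data.frame(gene = colnames(m), mean_rank = colMeans(ranks),
                    z = z, score = abs(z))
  out[order(-out$score), , drop = FALSE]
}

#' Sigmoid normalization of a regional map
#'
#' Z-scores the values and passes them through the logistic function
#' `1 / (1 + exp(-z))`; output lies strictly in (0, 1) and preserves rank
#' order.
#'
#' @param map A `regional_map` (or numeric vector); must not be constant.
#' @return A normalized `regional_map`.
#' @export
sigmoid_normalize <- function(map) {
  if (!inherits(map, "regional_map")) map <- regional_map(map)
  x <- map$values
  if (sd(x) == 0) stop("constant map cannot be sigmoid normalized")
  z <- (x - mean(x)) / sd(x)
  regional_map(1 / (1 + exp(-z)), labels = map$labels, normalized = TRUE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (delegates to
#' `p.adjust(method = "BH")` after validating the inputs).
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted q-values in the input order.
#' @export
fdr_bh <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}
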
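#' Regional timeseries container
#'
#' A time-by-regions real matrix with unique region labels and a sampling
#' interval, the object consumed by every information and energy measure in
#' the package.
#'
#' @param values Numeric matrix, rows are timepoints, columns are regions.
#' @param labels Character vector of unique region identifiers; defaults to
#'   column names or generated labels.
#' @param tr Sampling interval in seconds (must be positive).
#' @return An object of class `regional_timeseries` with elements `values`,
#'   `labels` and `tr`.
#' @export
regional_timeseries <- function(values, labels = NULL, tr = 1) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) stop("timeseries values must be finite")
  if (is.null(labels)) {
    labels <- colnames(values)
    if (is.null(labels)) labels <- default_labels(ncol(values))
  }
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) {
    stop("got ", length(labels), " labels for ", ncol(values), " regions")
  }
  if (anyDuplicated(labels)) stop("region labels must be unique")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) stop("tr must be > 0")
  colnames(values) <- labels
  structure(list(values = values, labels = labels, tr = as.numeric(tr)),
            class = "regional_timeseries")
}

#' @export
print.regional_timeseries <- function(x, ...) {
  cat(sprintf("<regional_timeseries> %d timepoints x %d regions, tr = %g s\n",
              nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

n_regions <- function(ts) ncol(ts$values)
n_timepoints <- function(ts) nrow(ts$values)

#' Weighted structural connectome
#'
#' Symmetric nonnegative weighted adjacency with zero diagonal, defining both
#' the control dynamics and the mean-field coupling.
#'
#' @param weights Square numeric matrix of nonnegative weights.
#' @param labels Region identifiers (defaults to row names or generated).
#' @return Object of class `connectome`.
#' @export
connectome <- function(weights, labels = NULL) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  stop_if_not_symmetric(weights, tol = 1e-8, what = "connectome weights")
  weights <- (weights + t(weights)) / 2
  if (any(weights < 0)) stop("connectome weights must be nonnegative")
  diag(weights) <- 0
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels)) labels <- default_labels(nrow(weights))
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(weights) || anyDuplicated(labels)) {
    stop("labels must be unique and match the connectome dimension")
  }
  dimnames(weights) <- list(labels, labels)
  # warn (not fail) when the graph is disconnected on its largest component
  deg <- rowSums(weights > 0)
  if (nrow(weights) > 1 && any(deg == 0)) {
    warning("connectome has isolated nodes; largest component does not cover all regions")
  }
  structure(list(weights = weights, labels = labels), class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  dens <- sum(x$weights[upper.tri(x$weights)] > 0) / (n * (n - 1) / 2)
  cat(sprintf("<connectome> %d regions, density %.3f\n", n, dens))
  invisible(x)
}

#' Regional scalar map
#'
#' Per-region scalar values (for example a gene-expression gradient), either
#' raw or normalized to the unit interval.
#'
#' @param values Numeric vector, one value per region.
#' @param labels Region identifiers.
#' @param normalized Logical flag; if `TRUE` values must lie in `[0, 1]`.
#' @return Object of class `regional_map`.
#' @export
regional_map <- function(values, labels = NULL, normalized = FALSE) {
  if (is.null(labels)) labels <- names(values)
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("map values must be finite")
  if (is.null(labels)) labels <- default_labels(length(values))
  labels <- as.character(labels)
  if (length(labels) != length(values) || anyDuplicated(labels)) {
    stop("labels must be unique and match the map length")
  }
  if (normalized && (any(values < 0) || any(values > 1))) {
    stop("normalized map must have values in [0, 1]")
  }
  names(values) <- labels
  structure(list(values = values, labels = labels, normalized = isTRUE(normalized)),
            class = "regional_map")
}

#' @export
print.regional_map <- function(x, ...) {
  cat(sprintf("<regional_map> %d regions, range [%.3g, %.3g]%s\n",
              length(x$values), min(x$values), max(x$values),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

read_delim_matrix <- function(path, sep = "\t") {
  df <- tryCatch(
    read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) stop("failed to read '", path, "': ", conditionMessage(e))
  )
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))
    stop("non-numeric cells in '", path, "' (columns: ",
         paste(names(df)[bad], collapse = ", "), ")")
  }
  m
}

#' Read / write regional timeseries
#'
#' Delimited text with a header row of region labels; rows are timepoints.
#' The sampling interval is carried in a `# tr:` comment line on write and
#' recovered on read (default 1 s when absent). Round trips are lossless to
#' below 1e-12.
#'
#' @param path File path.
#' @param sep Field delimiter (tab by default; comma accepted).
#' @param ts A `regional_timeseries` object.
#' @return `read_timeseries` returns a `regional_timeseries`.
#' @export
read_timeseries <- function(path, sep = "\t") {
  first <- readLines(path, n = 1L)
  tr <- 1
  skip <- 0L
  if (startsWith(first, "# tr:")) {
    tr <- as.numeric(trimws(sub("# tr:", "", first, fixed = TRUE)))
    skip <- 1L
  }
  df <- read.delim(path, sep = sep, header = TRUE, skip = skip,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cells in timeseries file '", path, "'")
  regional_timeseries(m, labels = colnames(df), tr = tr)
}

#' @rdname read_timeseries
#' @export
write_timeseries <- function(ts, path, sep = "\t") {
  stopifnot(inherits(ts, "regional_timeseries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# tr: ", format(ts$tr, digits = 17)), con)
  writeLines(paste(ts$labels, collapse = sep), con)
  write.table(format(ts$values, digits = 17, trim = TRUE, scientific = TRUE),
              con, sep = sep, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write connectomes
#'
#' Square delimited text with matching header and first column of labels.
#' Asymmetries beyond 1e-8 are rejected.
#'
#' @param path File path.
#' @param sep Field delimiter.
#' @param cn A `connectome` object.
#' @return `read_connectome` returns a `connectome`.
#' @export
read_connectome <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, header = TRUE, row.names = 1,
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cells in connectome file '", path, "'")
  if (nrow(m) != ncol(m)) stop("connectome in '", path, "' is not square")
  if (!identical(rownames(m), colnames(m))) {
    stop("connectome row labels do not match column labels in '", path, "'")
  }
  connectome(m, labels = colnames(m))
}

#' @rdname read_connectome
#' @export
write_connectome <- function(cn, path, sep = "\t") {
  stopifnot(inherits(cn, "connectome"))
  df <- data.frame(label = cn$labels,
                   format(cn$weights, digits = 17, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("label", cn$labels)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write regional maps
#'
#' Two-column delimited text (`label`, `value`) with a header row. Reading
#' against a reference label set reorders by label, never by position.
#'
#' @param path File path.
#' @param sep Field delimiter.
#' @param labels Optional reference label order to join against.
#' @param map A `regional_map`.
#' @return `read_map` returns a `regional_map`.
#' @export
read_map <- function(path, sep = "\t", labels = NULL) {
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!all(c("label", "value") %in% colnames(df))) {
    stop("map file '", path, "' must have 'label' and 'value' columns")
  }
  if (!is.numeric(df$value)) stop("non-numeric map values in '", path, "'")
  vals <- df$value
  labs <- as.character(df$label)
  if (!is.null(labels)) {
    idx <- match(labels, labs)
    if (anyNA(idx)) {
      stop("map file '", path, "' is missing labels: ",
           paste(labels[is.na(idx)], collapse = ", "))
    }
    vals <- vals[idx]
    labs <- labels
  }
  normalized <- all(vals >= 0 & vals <= 1)
  regional_map(vals, labels = labs, normalized = normalized)
}

#' @rdname read_map
#' @export
write_map <- function(map, path, sep = "\t") {
  stopifnot(inherits(map, "regional_map"))
  df <- data.frame(label = map$labels,
                   value = format(map$values, digits = 17, trim = TRUE,
                                  scientific = TRUE))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
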
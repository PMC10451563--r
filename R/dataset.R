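#' Continuous biological signal data sets
#'
#' A signal data set holds an `m x v` numeric matrix of measurements (rows are
#' samples, columns are biological nodes such as brain regions or proteins),
#' together with unique node labels. All entries must be finite.
#'
#' @param values numeric matrix, `m` samples by `v >= 2` nodes.
#' @param labels character vector of `v` unique node labels; defaults to the
#'   column names of `values` or `X1..Xv`.
#' @param source optional string tag identifying the origin of the data.
#' @return An object of class `"signal_dataset"` with fields `values`,
#'   `labels`, `source`.
#' @export
signal_dataset <- function(values, labels = NULL, source = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) stop("need at least one sample (row)")
  if (ncol(values) < 2L) stop("need at least two nodes (columns)")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite value at row ", bad[1L], ", column ", bad[2L])
  }
  if (is.null(labels)) labels <- colnames(values)
  if (is.null(labels)) labels <- paste0("X", seq_len(ncol(values)))
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) stop("one label per column required")
  if (anyDuplicated(labels)) stop("node labels must be unique")
  dimnames(values) <- list(NULL, labels)
  structure(list(values = values, labels = labels, source = source),
            class = "signal_dataset")
}

#' @export
print.signal_dataset <- function(x, ...) {
  cat("Signal data set", if (nzchar(x$source)) paste0("[", x$source, "]"),
      ":", nrow(x$values), "samples x", length(x$labels), "nodes\n")
  invisible(x)
}

#' @export
dim.signal_dataset <- function(x) dim(x$values)

#' Read a delimited signal table
#'
#' Parses a plain-text table of numeric signals (samples in rows, nodes in
#' columns). Every cell must parse as a finite number; the first line may be a
#' header of node labels.
#'
#' @param path path to the file.
#' @param delimiter field separator (default tab).
#' @param header `TRUE`, `FALSE`, or `"auto"` (default): detect a header by
#'   whether the first line parses as numbers.
#' @param source tag stored on the result; defaults to the file name.
#' @return A [signal_dataset()].
#' @export
read_signal_table <- function(path, delimiter = "\t", header = "auto",
                              source = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  split_row <- function(l) trimws(strsplit(l, delimiter, fixed = TRUE)[[1L]])
  first <- split_row(lines[1L])
  first_num <- suppressWarnings(as.numeric(first))
  has_header <- if (identical(header, "auto")) anyNA(first_num)
                else isTRUE(header)
  labels <- if (has_header) first else NULL
  body <- if (has_header) lines[-1L] else lines
  if (!length(body)) stop("no data rows in ", path)
  cells <- lapply(body, split_row)
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1L)
    stop("ragged table: rows have differing numbers of fields")
  if (ncols[1L] < 2L) stop("fewer than 2 columns in ", path)
  vals <- matrix(NA_real_, nrow = length(cells), ncol = ncols[1L])
  for (i in seq_along(cells)) {
    x <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(x) || any(!is.finite(x))) {
      j <- which(is.na(x) | !is.finite(x))[1L]
      stop("cannot parse cell at data row ", i, ", column ", j,
           " ('", cells[[i]][j], "') as a finite number")
    }
    vals[i, ] <- x
  }
  signal_dataset(vals, labels = labels, source = source)
}

#' Write a signal data set to a delimited table
#'
#' @param x a [signal_dataset()].
#' @param path output file path.
#' @param delimiter field separator (default tab).
#' @export
write_signal_table <- function(x, path, delimiter = "\t") {
  stopifnot(inherits(x, "signal_dataset"))
  utils::write.table(x$values, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = x$labels)
  invisible(path)
}

#' Equal-frequency discretization of continuous signals
#'
#' Maps each column of a signal data set independently onto `bins`
#' equal-frequency levels using sample quantiles, the categorical form the K2
#' metric requires. Values tied with an interior bin boundary are assigned to
#' the lower bin. Columns with at most `bins` distinct values are passed
#' through unchanged (rank-coded), so exactly discrete inputs are not
#' distorted; a constant column collapses to a single level with a warning.
#'
#' @param x a [signal_dataset()] or numeric matrix.
#' @param bins number of levels per node (default 3, the usual convention for
#'   discretized biological signal benchmarks); must be at least 2.
#' @return An object of class `"discrete_dataset"`: list with `levels`
#'   (integer matrix of 0-based level codes), `cardinalities` (realized level
#'   counts per node), `labels`.
#' @examples
#' d <- discretize(signal_dataset(cbind(a = 1:6, b = c(2, 1, 2, 1, 2, 1))))
#' d$levels
#' @export
discretize <- function(x, bins = 3L) {
  if (!inherits(x, "signal_dataset")) x <- signal_dataset(x)
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be at least 2")
  m <- nrow(x$values); v <- ncol(x$values)
  lev <- matrix(0L, m, v, dimnames = list(NULL, x$labels))
  cards <- integer(v)
  for (j in seq_len(v)) {
    col <- x$values[, j]
    ux <- unique(col)
    if (length(ux) <= bins) {
      if (length(ux) == 1L)
        warning("column '", x$labels[j],
                "' is constant; coded as a single level")
      code <- match(col, sort(ux)) - 1L
    } else {
      br <- stats::quantile(col, probs = seq_len(bins - 1L) / bins,
                            names = FALSE, type = 7)
      raw <- rowSums(outer(col, br, `>`))  # ties at a boundary go lower
      realized <- sort(unique(raw))
      code <- match(raw, realized) - 1L
    }
    lev[, j] <- as.integer(code)
    cards[j] <- max(code) + 1L
  }
  structure(list(levels = lev, cardinalities = cards, labels = x$labels),
            class = "discrete_dataset")
}

#' @export
print.discrete_dataset <- function(x, ...) {
  cat("Discrete data set:", nrow(x$levels), "samples x", length(x$labels),
      "nodes; cardinalities:",
      paste(x$cardinalities, collapse = " "), "\n")
  invisible(x)
}

# Coerce to discrete_dataset, discretizing if needed.
as_discrete <- function(x, bins = 3L) {
  if (inherits(x, "discrete_dataset")) x else discretize(x, bins = bins)
}
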
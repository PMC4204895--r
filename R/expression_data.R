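#' Time-series expression matrix with day coordinates
#'
#' Container for a gene x timepoint expression matrix sampled on a (possibly
#' irregular) grid of days.  Day 0 is the induction of differentiation;
#' negative days (e.g. -2, proliferating cells) are allowed.  All values are
#' clipped from below at `floor`, emulating the truncation applied to
#' RMA-normalised microarray intensities upstream.
#'
#' @param values numeric matrix, genes in rows (rownames are gene ids),
#'   timepoints in columns.
#' @param times numeric vector of days, strictly increasing, one per column.
#' @param floor non-negative scalar; values below it are raised to it.
#'   Default 20, the truncation floor of the adipogenesis arrays.
#' @return An object of class `expression_series`: a list with elements
#'   `genes`, `times`, `values` (floored matrix) and `floor`.
#' @examples
#' m <- matrix(c(10, 40, 80, 120, 30, 25, 22, 21), 2, 4, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), NULL))
#' es <- expression_series(m, times = c(-2, 0, 2, 7))
#' es$values["g1", 1]  # 20: clipped at the floor
#' @export
expression_series <- function(values, times, floor = 20) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  times <- as.numeric(times)
  if (length(times) < 2L)
    stop("InsufficientData: need at least two timepoints")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (ncol(values) != length(times))
    stop("ncol(values) must equal length(times)")
  if (is.null(rownames(values)))
    stop("values must carry gene ids as rownames")
  if (anyDuplicated(rownames(values)))
    stop("DuplicateGene: duplicated gene ids")
  if (anyNA(values) || any(!is.finite(values)))
    stop("ParseError: missing or non-finite expression values")
  if (!is.numeric(floor) || length(floor) != 1L || floor < 0)
    stop("floor must be a non-negative scalar")
  values[values < floor] <- floor
  colnames(values) <- as.character(times)
  structure(list(genes = rownames(values), times = times,
                 values = values, floor = floor),
            class = "expression_series")
}

#' @export
print.expression_series <- function(x, ...) {
  cat(sprintf("expression_series: %d genes x %d timepoints (days %s..%s), floor %g\n",
              length(x$genes), length(x$times),
              format(min(x$times)), format(max(x$times)), x$floor))
  invisible(x)
}

#' Read an expression matrix from a delimited file
#'
#' Expects a header row of numeric day labels (negative days allowed) and a
#' first column of unique gene ids.  The field separator is taken from the
#' file extension (`.csv` is comma, anything else tab) unless given.
#'
#' @param path path to a TSV/CSV table.
#' @param floor truncation floor applied after parsing (default 20).
#' @param sep optional field separator overriding extension detection.
#' @return An [expression_series()].
#' @export
load_expression <- function(path, floor = 20, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L)
    stop("InsufficientData: fewer than two timepoints in ", path)
  genes <- tab[[1L]]
  if (anyDuplicated(genes))
    stop("DuplicateGene: duplicated gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  times <- suppressWarnings(as.numeric(colnames(tab)[-1L]))
  if (anyNA(times))
    stop("ParseError: non-numeric day label in header")
  vals <- suppressWarnings(vapply(tab[-1L], as.numeric, numeric(nrow(tab))))
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(genes, colnames(tab)[-1L]))
  if (anyNA(vals))
    stop("ParseError: non-numeric expression value")
  expression_series(vals, times, floor = floor)
}

#' Write an expression series back to a delimited file
#'
#' @param series an [expression_series()].
#' @param path output path; `.csv` writes comma-separated, else tab.
#' @param sep optional separator override.
#' @export
write_expression <- function(series, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- data.frame(gene = series$genes, series$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("gene", as.character(series$times))
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Piecewise-linear interpolation onto a denser time grid
#'
#' Reconstructs expression at intermediate days by linear interpolation per
#' gene, the device used to densify sparse (mouse-style, 4-point) grids
#' before fitting.  Values at observed days are preserved exactly;
#' extrapolation outside the observed range is refused.
#'
#' @param series an [expression_series()].
#' @param target_times days to evaluate at; must lie within
#'   `range(series$times)`.
#' @return An [expression_series()] on `sort(unique(target_times))`.
#' @export
interpolate_series <- function(series, target_times) {
  stopifnot(inherits(series, "expression_series"))
  target_times <- sort(unique(as.numeric(target_times)))
  if (length(target_times) < 2L)
    stop("InsufficientData: need at least two target times")
  if (min(target_times) < min(series$times) ||
      max(target_times) > max(series$times))
    stop("ExtrapolationError: target times outside observed range [",
         min(series$times), ", ", max(series$times), "]")
  vals <- t(vapply(seq_along(series$genes), function(i)
    stats::approx(series$times, series$values[i, ], xout = target_times)$y,
    numeric(length(target_times))))
  keep <- match(series$times, target_times)
  ok <- !is.na(keep)
  vals[, keep[ok]] <- series$values[, ok]
  dimnames(vals) <- list(series$genes, as.character(target_times))
  out <- expression_series(vals, target_times, floor = series$floor)
  attr(out, "interpolated") <- !(target_times %in% series$times)
  out
}

#' Mean-over-standard-deviation feature scaling
#'
#' Rescales each feature (row) by the factor mean/sd, i.e. divides by the
#' standard deviation and multiplies by the mean, so that highly expressed
#' genes keep their weight after variance standardisation.  The sample
#' (n-1) standard deviation is used.  Constant rows (sd = 0, e.g. genes
#' stuck at the truncation floor) pass through unchanged and are flagged
#' degenerate.
#'
#' @param values numeric matrix, features in rows, >= 2 columns.
#' @return list with `values` (scaled matrix) and `scale`, a data frame of
#'   per-feature factors usable with [denormalize_features()].
#' @export
normalize_features <- function(values) {
  values <- as.matrix(values)
  if (length(values) == 0L)
    stop("EmptyInput: empty matrix")
  if (ncol(values) < 2L)
    stop("InsufficientData: each feature needs >= 2 samples")
  m <- rowMeans(values)
  s <- apply(values, 1L, stats::sd)
  degenerate <- s == 0
  f <- ifelse(degenerate, 1, m / s)
  out <- values * f
  feat <- rownames(values)
  if (is.null(feat)) feat <- as.character(seq_len(nrow(values)))
  list(values = out,
       scale = data.frame(feature = feat, factor = f,
                          degenerate = degenerate,
                          row.names = NULL, stringsAsFactors = FALSE))
}

#' Invert the scaling applied by [normalize_features()]
#'
#' @param values scaled matrix.
#' @param scale the `scale` record returned by [normalize_features()].
#' @return matrix on the original scale.
#' @export
denormalize_features <- function(values, scale) {
  as.matrix(values) / scale$factor
}

#' Serialize / read a feature-scale record as a key-value text file
#'
#' @param scale scale record from [normalize_features()].
#' @param path file path.
#' @export
write_scale_record <- function(scale, path) {
  utils::write.table(scale, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_scale_record
#' @export
read_scale_record <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
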
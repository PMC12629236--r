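#' Read a taxon count table
#'
#' Reads a TSV/CSV count table with a header row of taxon identifiers and a
#' first column of sample identifiers. Orientation is samples in rows, taxa
#' in columns; use `transpose = TRUE` for taxa-in-rows files.
#'
#' @param path Path to a TSV or CSV file (delimiter inferred from extension).
#' @param transpose If `TRUE`, the file stores taxa in rows and samples in
#'   columns and is transposed after reading.
#' @return A numeric matrix of non-negative counts with sample row names and
#'   taxon column names.
#' @export
read_counts <- function(path, transpose = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (transpose) m <- t(m)
  validate_counts(m)
  m
}

#' Read sample metadata keyed by sample identifier
#'
#' @param path TSV/CSV file whose first column holds sample identifiers.
#' @return A tibble with a `sample` column followed by the metadata columns.
#' @export
read_metadata <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- "sample"
  tibble::as_tibble(df)
}

validate_counts <- function(counts) {
  if (any(is.na(counts))) abort("count table contains missing values")
  if (any(counts < 0)) abort("count table contains negative entries")
  if (!is.null(colnames(counts)) && anyDuplicated(colnames(counts))) {
    abort("taxon identifiers must be unique")
  }
  invisible(counts)
}

#' Close a count table into compositions with a pseudo-count
#'
#' Adds `pseudo_count` to every entry and renormalizes each sample's row to
#' sum to one, placing it strictly inside the simplex. The pseudo-count is
#' applied to all entries (not only zeros); the default of 0.5 is the usual
#' choice for 16S count tables.
#'
#' @param counts Non-negative count matrix (samples in rows) or a data frame
#'   with a leading sample-identifier column.
#' @param pseudo_count Non-negative value added to every count before
#'   closure. Must be positive when any count is zero.
#' @return A numeric matrix of proportions with attribute `pseudo_count`;
#'   every row sums to one.
#' @export
#' @examples
#' close_counts(matrix(c(1, 1, 2), 1), pseudo_count = 0.5)
close_counts <- function(counts, pseudo_count = 0.5) {
  counts <- as_numeric_matrix(counts, "counts")
  validate_counts(counts)
  if (pseudo_count < 0) abort("pseudo_count must be non-negative")
  if (pseudo_count == 0 && any(counts == 0)) {
    abort("zero counts present: a positive pseudo_count is required")
  }
  w <- counts + pseudo_count
  rs <- rowSums(w)
  if (any(rs <= 0)) abort("row with non-positive total after pseudo-count")
  x <- w / rs
  attr(x, "pseudo_count") <- pseudo_count
  x
}

#' Centered log-ratio transform
#'
#' Maps each compositional row `x_i` to `log(x_ij / g(x_i))` where `g` is
#' the row geometric mean. Rows of the result sum to zero: CLR coordinates
#' live on a zero-sum hyperplane, which is why downstream regression carries
#' a sum-to-zero constraint on its coefficients.
#'
#' @param x Strictly positive composition matrix (rows sum to 1), e.g. from
#'   [close_counts()].
#' @return A numeric matrix of CLR coordinates with attribute
#'   `geometric_means` (per-row geometric means).
#' @export
clr_transform <- function(x) {
  x <- as_numeric_matrix(x, "compositions")
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-positive entry at row %d, column %d: CLR undefined",
                  bad[1, 1], bad[1, 2]))
  }
  lx <- log(x)
  gm <- rowMeans(lx)
  z <- lx - gm
  attr(z, "geometric_means") <- exp(gm)
  z
}
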
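#' @importFrom stats coef cov lm rnorm runif rgamma sd setNames var
#' @importFrom rlang %||% abort warn .data
#' @useDynLib tcvs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Coerce a counts/metadata input (matrix, data.frame, tibble) to a numeric
# matrix. A leading character/factor column is treated as row identifiers.
as_numeric_matrix <- function(x, what = "input") {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.data.frame(x)) {
    x <- as.data.frame(x)
    if (ncol(x) > 0 && (is.character(x[[1]]) || is.factor(x[[1]]))) {
      ids <- as.character(x[[1]])
      x <- x[, -1, drop = FALSE]
      m <- as.matrix(x)
      rownames(m) <- ids
    } else {
      m <- as.matrix(x)
    }
    if (!is.numeric(m)) {
      abort(sprintf("%s contains non-numeric columns", what))
    }
    storage.mode(m) <- "double"
    return(m)
  }
  abort(sprintf("%s must be a matrix or data frame", what))
}

# Deterministic per-replicate seed stream derived from a master seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seeds <- function(master, n) {
  master <- as.numeric(master)
  ((master * 7919 + seq_len(n) * 104729) %% 2147483629) + 1
}

center_columns <- function(m) {
  mu <- colMeans(m)
  list(values = sweep(m, 2, mu, "-"), center = mu)
}
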
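#' Knockoff statistics from an augmented fit
#'
#' The statistic for taxon `j` contrasts original and knockoff coefficient
#' magnitudes from a single augmented fit: `w_j = |beta_j| - |beta~_j|`.
#' Large positive values indicate genuine signal; under the null, signs are
#' symmetric.
#'
#' @param fit A `tcvs_fit` with knockoff coefficients.
#' @return A `knockoff_stats` object: `w` and the sorted distinct nonzero
#'   `|w|` candidate thresholds.
#' @export
knockoff_statistics <- function(fit) {
  stopifnot(inherits(fit, "tcvs_fit"))
  if (is.null(fit$beta_tilde)) {
    abort("fit has no knockoff coefficients; fit with z_tilde first")
  }
  w <- abs(fit$beta) - abs(fit$beta_tilde)
  structure(list(w = w, nonzero_abs = sort(unique(abs(w[w != 0])))),
            class = "knockoff_stats")
}

#' Data-dependent knockoff selection threshold
#'
#' Returns `T = min{ t in candidates : #{j : w_j <= -t} /
#' max(1, #{j : w_j >= t}) <= q }`, where the candidates are the distinct
#' nonzero `|w_j|`. `+Inf` (empty selection) when no candidate qualifies.
#' `plus = TRUE` adds 1 to the numerator (the more conservative variant);
#' the default is the plain ratio.
#'
#' @param stats A `knockoff_stats` object or a numeric vector of statistics.
#' @param q Target level in (0, 1).
#' @param plus Use the +1 numerator correction (default `FALSE`).
#' @return The threshold (possibly `Inf`).
#' @export
knockoff_threshold <- function(stats, q = 0.05, plus = FALSE) {
  if (q <= 0 || q >= 1) abort("q must lie strictly between 0 and 1")
  w <- if (inherits(stats, "knockoff_stats")) stats$w else as.numeric(stats)
  cand <- sort(unique(abs(w[w != 0])))
  if (length(cand) == 0) return(Inf)
  for (t in cand) {
    num <- sum(w <= -t) + if (plus) 1 else 0
    den <- max(1, sum(w >= t))
    if (num / den <= q) return(t)
  }
  Inf
}

#' BIC for a penalized augmented fit
#'
#' `BIC = n log(RSS / n) + K log(n)` where `RSS` is the residual sum of
#' squares of the (augmented) fit and `K` counts nonzero coefficients of the
#' full penalized vector — original plus knockoff when present.
#'
#' @param y Response vector.
#' @param design Design matrix used in the fit (augmented when knockoffs are
#'   present), on the same centering as `coeffs`.
#' @param coeffs Penalized coefficient vector matching `design`.
#' @return The BIC value (`-Inf` with a warning for a zero-residual fit).
#' @export
bic_score <- function(y, design, coeffs) {
  n <- length(y)
  rss <- sum((y - as.matrix(design) %*% coeffs)^2)
  k <- sum(coeffs != 0)
  if (rss <= 0) {
    warn("zero residual: saturated fit, BIC is -Inf")
    return(-Inf)
  }
  n * log(rss / n) + k * log(n)
}

bic_of_fit <- function(fit, y, z, z_tilde = NULL, covariates = NULL) {
  yhat <- fit$intercept + z %*% fit$beta
  if (!is.null(z_tilde)) yhat <- yhat + z_tilde %*% fit$beta_tilde
  if (!is.null(fit$gamma)) yhat <- yhat + as.matrix(covariates) %*% fit$gamma
  rss <- sum((y - yhat)^2)
  k <- sum(fit$beta != 0) +
    if (is.null(fit$beta_tilde)) 0L else sum(fit$beta_tilde != 0)
  n <- length(y)
  if (rss <= 0) {
    warn("zero residual: saturated fit, BIC is -Inf")
    return(list(bic = -Inf, df = k))
  }
  list(bic = n * log(rss / n) + k * log(n), df = k)
}

#' Tune lambda by BIC along a warm-started path
#'
#' Fits the model on a descending lambda grid (warm starts between adjacent
#' values) and picks the lambda minimizing the BIC; ties break toward the
#' larger lambda (the sparser model). The default grid is `nlambda`
#' log-spaced points from the data-derived `lambda_max` down to
#' `lambda_min_ratio * lambda_max`.
#'
#' @inheritParams tcvs_fit
#' @param grid Optional explicit lambda grid (any order; sorted internally).
#' @param nlambda Grid length (default 50).
#' @param lambda_min_ratio Smallest grid value relative to the maximum
#'   (default 0.001).
#' @return A list: `lambda_opt`, `fit` (the fit at `lambda_opt`),
#'   `bic_table` (tibble of lambda, bic, support size, convergence).
#' @export
tune_lambda <- function(y, z, z_tilde = NULL, gs = NULL, covariates = NULL,
                        grid = NULL, nlambda = 50, lambda_min_ratio = 0.001,
                        control = list()) {
  if (is.null(grid)) {
    lmax <- lambda_max(y, z, z_tilde, covariates)
    grid <- exp(seq(log(lmax), log(lambda_min_ratio * lmax),
                    length.out = nlambda))
  }
  if (length(grid) == 0 || any(grid <= 0)) abort("lambda grid must be positive")
  grid <- sort(unique(grid), decreasing = TRUE)
  fits <- vector("list", length(grid))
  bics <- dfs <- numeric(length(grid))
  warm <- NULL
  for (i in seq_along(grid)) {
    fits[[i]] <- tcvs_fit(y, z, z_tilde = z_tilde, gs = gs, lambda = grid[i],
                          covariates = covariates,
                          control = utils::modifyList(list(trace = FALSE),
                                                      control),
                          warm = warm)
    warm <- fits[[i]]$warm
    sc <- bic_of_fit(fits[[i]], y, z, z_tilde, covariates)
    bics[i] <- sc$bic
    dfs[i] <- sc$df
  }
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(conv)) abort("no lambda on the grid produced a converged fit")
  usable <- which(conv)
  best <- usable[which.min(bics[usable])]  # grid descending: ties keep sparser
  list(lambda_opt = grid[best],
       fit = fits[[best]],
       bic_table = tibble::tibble(lambda = grid, bic = bics, df = dfs,
                                  converged = conv))
}

#' Run the full tree-guided compositional variable selection pipeline
#'
#' End-to-end pipeline on a count table: pseudo-count closure, CLR
#' transform, tree groups, Gaussian model-X knockoffs, BIC-tuned constrained
#' sparse group lasso on the augmented design, knockoff statistics,
#' threshold, and the selected taxon set. Ablation variants: `"tlasso"`
#' (tree penalty, no knockoffs), `"classokf"` (knockoffs, no tree penalty),
#' `"classo"` (neither); the no-knockoff variants return the BIC-selected
#' support directly.
#'
#' @param counts Count matrix (samples x taxa) or data frame with a leading
#'   sample-identifier column.
#' @param tree A `taxonomic_tree` (required for tree-guided variants).
#' @param y Numeric response vector.
#' @param covariates Optional unpenalized covariate matrix/data frame.
#' @param variant One of `"tcvs"`, `"tlasso"`, `"classokf"`, `"classo"`.
#' @param q Knockoff threshold level (default 0.05).
#' @param pseudo_count Closure pseudo-count (default 0.5).
#' @param seed Integer seed for knockoff sampling.
#' @param knockoff_method `"equi"` or `"sdp"`.
#' @param include_root Keep the root group (see [build_groups()]).
#' @param nlambda,lambda_min_ratio,grid Lambda grid controls
#'   (see [tune_lambda()]).
#' @param control Solver control list passed to [tcvs_fit()].
#' @return A `tcvs_selection`: a per-taxon tibble (`taxon`, `beta`,
#'   `beta_tilde`, `w`, `selected`), the threshold, `lambda_opt`, the BIC
#'   table, the underlying fit and configuration.
#' @export
run_tcvs <- function(counts, tree = NULL, y, covariates = NULL,
                     variant = c("tcvs", "tlasso", "classokf", "classo"),
                     q = 0.05, pseudo_count = 0.5, seed = 1,
                     knockoff_method = c("equi", "sdp"), include_root = TRUE,
                     nlambda = 50, lambda_min_ratio = 0.001, grid = NULL,
                     control = list()) {
  variant <- match.arg(variant)
  knockoff_method <- match.arg(knockoff_method)
  uses_tree <- variant %in% c("tcvs", "tlasso")
  uses_kn <- variant %in% c("tcvs", "classokf")
  counts <- as_numeric_matrix(counts, "counts")
  if (length(y) != nrow(counts)) abort("length(y) does not match sample count")
  if (uses_tree && is.null(tree)) {
    abort(sprintf("variant '%s' requires a taxonomic tree", variant))
  }
  if (!is.null(covariates)) covariates <- as_numeric_matrix(covariates,
                                                            "covariates")
  x <- close_counts(counts, pseudo_count)
  z <- clr_transform(x)
  p <- ncol(z)
  taxa <- colnames(z) %||% paste0("taxon", seq_len(p))

  gs <- if (uses_tree) build_groups(tree, include_root = include_root)
  kn <- NULL
  z_tilde <- NULL
  if (uses_kn) {
    kn <- create_knockoffs(z, method = knockoff_method, seed = seed)
    z_tilde <- kn$z_tilde
    if (uses_tree) gs <- augment_groups(gs)
  }
  tuned <- tune_lambda(y, z, z_tilde = z_tilde, gs = gs,
                       covariates = covariates, grid = grid,
                       nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                       control = control)
  fit <- tuned$fit

  if (uses_kn) {
    stats <- knockoff_statistics(fit)
    threshold <- knockoff_threshold(stats, q = q)
    selected <- which(stats$w >= threshold)
    w <- stats$w
  } else {
    w <- rep(NA_real_, p)
    threshold <- NA_real_
    selected <- which(fit$beta != 0)
  }
  result <- tibble::tibble(
    taxon = taxa, index = seq_len(p), beta = unname(fit$beta),
    beta_tilde = if (uses_kn) fit$beta_tilde else rep(NA_real_, p),
    w = w, selected = seq_len(p) %in% selected)
  structure(list(result = result, selected = selected,
                 threshold = threshold, q = q,
                 lambda_opt = tuned$lambda_opt, bic_table = tuned$bic_table,
                 fit = fit, knockoffs = kn, variant = variant, seed = seed),
            class = "tcvs_selection")
}

#' @export
print.tcvs_selection <- function(x, ...) {
  cat(sprintf("%s selection: %d of %d taxa (q = %g, lambda_opt = %.4g%s)\n",
              x$variant, length(x$selected), nrow(x$result), x$q,
              x$lambda_opt,
              if (!is.na(x$threshold))
                sprintf(", threshold = %s",
                        if (is.finite(x$threshold))
                          sprintf("%.4g", x$threshold) else "Inf")
              else ""))
  if (length(x$selected) > 0) {
    cat("  ", paste(x$result$taxon[x$selected], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a selection result
#'
#' @param x A `tcvs_selection`.
#' @param ... Unused.
#' @return The per-taxon tibble (taxon, index, beta, beta_tilde, w,
#'   selected).
#' @method tidy tcvs_selection
#' @export
tidy.tcvs_selection <- function(x, ...) x$result

#' Selection-level summary
#'
#' @param x A `tcvs_selection`.
#' @param ... Unused.
#' @return A one-row tibble: variant, q, threshold, lambda_opt, counts.
#' @method glance tcvs_selection
#' @export
glance.tcvs_selection <- function(x, ...) {
  tibble::tibble(variant = x$variant, q = x$q, threshold = x$threshold,
                 lambda_opt = x$lambda_opt, n_selected = length(x$selected),
                 p = nrow(x$result), seed = x$seed)
}

#' Plot knockoff statistics with the selection threshold
#'
#' @param object A `tcvs_selection` from a knockoff variant.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tcvs_selection
#' @export
autoplot.tcvs_selection <- function(object, ...) {
  df <- object$result
  if (all(is.na(df$w))) {
    df$w <- df$beta  # no knockoffs: show coefficients instead
    ylab <- "coefficient"
  } else ylab <- "knockoff statistic W"
  pl <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$w,
                                         colour = .data$selected)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$index, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "taxon index", y = ylab) +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold) && is.finite(object$threshold)) {
    pl <- pl + ggplot2::geom_hline(yintercept = object$threshold,
                                   linetype = "dashed")
  }
  pl
}

#' Write selection outputs to a directory
#'
#' Writes `selected.tsv` (per-taxon table) and `fit.json` (lambda grid, BIC
#' values, diagnostics) under `dir`.
#'
#' @param x A `tcvs_selection`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_selection <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(x$result),
                     file.path(dir, "selected.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  diag <- list(variant = x$variant, q = x$q, seed = x$seed,
               lambda_opt = x$lambda_opt,
               threshold = if (is.finite(x$threshold)) x$threshold else "Inf",
               n_selected = length(x$selected),
               converged = x$fit$converged,
               constraint_violation = x$fit$constraint_violation,
               bic_table = as.data.frame(x$bic_table))
  jsonlite::write_json(diag, file.path(dir, "fit.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
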
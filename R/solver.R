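#' Exact proximal operator of the tree-guided penalty
#'
#' Computes `argmin_b 0.5 ||b - u||^2 + tau (||b||_1 + sum_v ||b[g_v]||/w_v)`
#' by composing elementwise soft-thresholding with per-group
#' soft-thresholding in leaf-to-root order, which is exact when the groups
#' form a laminar family (tree-nested sets).
#'
#' @param u Numeric vector.
#' @param gs A `tcvs_groups` object (or `NULL` for the plain lasso prox).
#' @param tau Non-negative threshold (step size times lambda).
#' @param l1_weights Per-coordinate lasso weights (default 1 everywhere).
#' @return The prox point, same length as `u`.
#' @export
hierarchical_prox <- function(u, gs = NULL, tau, l1_weights = NULL) {
  if (tau < 0) abort("tau must be non-negative")
  d <- length(u)
  if (is.null(l1_weights)) l1_weights <- rep(1, d)
  gl <- groups_for_solver(gs, d)
  as.numeric(.hier_prox_cpp(u, gl$idx0, gl$w, l1_weights, tau))
}

# groups as 0-based index vectors sorted children-before-parents
groups_for_solver <- function(gs, d) {
  if (is.null(gs)) return(list(idx0 = list(), w = numeric(0)))
  stopifnot(inherits(gs, "tcvs_groups"))
  expected <- gs$p * (1L + gs$augmented)
  if (expected > d) abort("group dimension exceeds design dimension")
  check_laminar(gs$members, expected)
  ord <- order(lengths(gs$members))
  list(idx0 = lapply(gs$members[ord], function(m) as.integer(m - 1L)),
       w = gs$weights[ord])
}

#' Penalized objective value
#'
#' Evaluates `(1/2n) ||y - D b||^2 + lambda (sum_j l1w_j |b_j| +
#' sum_v ||b[g_v]||/w_v)` for a coefficient vector `b` on the design `D`
#' (which may be the augmented `[Z, Z~]` matrix).
#'
#' @param y Response vector.
#' @param design Design matrix.
#' @param coeffs Coefficient vector.
#' @param gs Group structure or `NULL`.
#' @param lambda Penalty level.
#' @param l1_weights Per-coordinate lasso weights (default 1).
#' @return The objective value.
#' @export
tcvs_objective <- function(y, design, coeffs, gs = NULL, lambda,
                           l1_weights = NULL) {
  design <- as.matrix(design)
  if (length(y) != nrow(design) || length(coeffs) != ncol(design)) {
    abort("dimension mismatch between y, design and coeffs")
  }
  if (is.null(l1_weights)) l1_weights <- rep(1, ncol(design))
  gl <- groups_for_solver(gs, ncol(design))
  .objective_cpp(design, y, coeffs, gl$idx0, gl$w, l1_weights, lambda)
}

#' Largest useful penalty level
#'
#' Returns `max_j |d_j' r| / n` over penalized columns, where `r` is the
#' centered response (residualized on unpenalized covariates when present).
#' At this lambda the penalized solution is identically zero.
#'
#' @inheritParams tcvs_fit
#' @return A positive scalar.
#' @export
lambda_max <- function(y, z, z_tilde = NULL, covariates = NULL) {
  d <- cbind(z, z_tilde)
  d <- scale(d, center = TRUE, scale = FALSE)
  r <- y - mean(y)
  if (!is.null(covariates)) {
    cc <- scale(as.matrix(covariates), center = TRUE, scale = FALSE)
    r <- stats::lm.fit(cc, r)$residuals
  }
  max(abs(crossprod(d, r))) / length(y)
}

#' Fit the constrained sparse group lasso
#'
#' Solves the sum-to-zero-constrained sparse group lasso over the CLR design
#' `z` (tree-guided variant), optionally augmented with knockoff columns
#' `z_tilde` (each with its own sum-to-zero constraint block, and group
#' norms coupling original and knockoff coefficients of the same subtree).
#' With `gs = NULL` the fit reduces to the constrained lasso; with `z_tilde`
#' and `gs = NULL`, to its knockoff-augmented version. The intercept is
#' handled by centering and never penalized or constrained; optional
#' covariates are appended unpenalized and unconstrained.
#'
#' Optimization is two-block ADMM: a smooth-loss-plus-affine-projection
#' block (KKT linear solve) and the exact hierarchical prox block.
#'
#' @param y Response vector, length n.
#' @param z CLR matrix (n x p).
#' @param z_tilde Optional knockoff matrix (n x p).
#' @param gs Optional `tcvs_groups`; must be augmented when `z_tilde` is
#'   given (plain when not).
#' @param lambda Non-negative penalty level.
#' @param covariates Optional numeric matrix of unpenalized covariates.
#' @param constrain If `FALSE`, drop the zero-sum constraints (used for
#'   unconstrained reductions and checks).
#' @param control List of solver settings: `rho`, `maxit`, `abstol`,
#'   `reltol`, `zero_tol` (support cutoff), `trace` (record the objective
#'   each iteration).
#' @param warm Optional warm start (list with `z`, `u`) from a previous fit.
#' @return A `tcvs_fit` with elements `beta`, `beta_tilde`, `gamma`
#'   (covariate coefficients), `intercept`, `lambda`, `objective`,
#'   `objective_trace`, `converged`, `iterations`, `constraint_violation`
#'   (of the returned coefficients) and `pre_polish_violation` (the ADMM
#'   residual before the exact block re-centering).
#' @export
tcvs_fit <- function(y, z, z_tilde = NULL, gs = NULL, lambda,
                     covariates = NULL, constrain = TRUE,
                     control = list(), warm = NULL) {
  if (lambda < 0) abort("lambda must be non-negative")
  ctrl <- utils::modifyList(
    list(rho = 1, maxit = 10000L, abstol = 1e-8, reltol = 1e-6,
         zero_tol = 1e-8, trace = TRUE), control)
  z <- as_numeric_matrix(z, "z")
  n <- nrow(z)
  p <- ncol(z)
  if (length(y) != n) abort("length(y) does not match nrow(z)")
  has_kn <- !is.null(z_tilde)
  if (has_kn) {
    z_tilde <- as_numeric_matrix(z_tilde, "z_tilde")
    stopifnot(dim(z_tilde)[1] == n, dim(z_tilde)[2] == p)
  }
  if (!is.null(gs)) {
    if (has_kn && !gs$augmented) abort("groups must be augmented when z_tilde is given")
    if (!has_kn && gs$augmented) abort("augmented groups require z_tilde")
  }
  ncov <- 0L
  if (!is.null(covariates)) {
    covariates <- as_numeric_matrix(covariates, "covariates")
    ncov <- ncol(covariates)
  }
  d_raw <- cbind(z, if (has_kn) z_tilde, covariates)
  cc <- center_columns(d_raw)
  ybar <- mean(y)
  yc <- y - ybar
  d <- cc$values
  dtot <- ncol(d)
  npen <- p * (1L + has_kn)
  l1w <- c(rep(1, npen), rep(0, ncov))
  gl <- groups_for_solver(gs, dtot)
  blocks <- if (constrain) {
    if (has_kn) list(0:(p - 1L), p:(2L * p - 1L)) else list(0:(p - 1L))
  } else list()

  z0 <- warm$z %||% rep(0, dtot)
  u0 <- warm$u %||% rep(0, dtot)
  res <- .admm_solve_cpp(d, yc, gl$idx0, gl$w, l1w, blocks, lambda,
                         ctrl$rho, as.integer(ctrl$maxit), ctrl$abstol,
                         ctrl$reltol, z0, u0, isTRUE(ctrl$trace))
  if (!res$converged) {
    warn(sprintf("solver did not converge in %d iterations (lambda = %.4g)",
                 ctrl$maxit, lambda))
  }
  b <- as.numeric(res$z)
  b[abs(b) < ctrl$zero_tol] <- 0
  raw_viol <- if (constrain) {
    max(vapply(blocks, function(ix) abs(sum(b[ix + 1L])), numeric(1)))
  } else 0
  if (constrain) {
    # feasibility polish: re-center the active coefficients of each block so
    # the zero-sum constraint holds exactly without disturbing the support
    for (ix in blocks) {
      act <- ix[b[ix + 1L] != 0] + 1L
      if (length(act) > 0) b[act] <- b[act] - sum(b[act]) / length(act)
    }
  }
  viol <- if (constrain) {
    max(vapply(blocks, function(ix) abs(sum(b[ix + 1L])), numeric(1)))
  } else 0
  beta <- b[seq_len(p)]
  beta_tilde <- if (has_kn) b[p + seq_len(p)] else NULL
  gamma <- if (ncov > 0) b[npen + seq_len(ncov)] else NULL
  obj <- .objective_cpp(d, yc, b, gl$idx0, gl$w, l1w, lambda)
  structure(list(
    beta = stats::setNames(beta, colnames(z)),
    beta_tilde = beta_tilde,
    gamma = gamma,
    intercept = ybar - sum(cc$center * b),
    lambda = lambda,
    objective = obj,
    objective_trace = as.numeric(res$objective_trace),
    converged = res$converged,
    iterations = res$iterations,
    constraint_violation = viol,
    pre_polish_violation = raw_viol,
    warm = list(z = as.numeric(res$z), u = as.numeric(res$u)),
    n = n, p = p, has_knockoffs = has_kn),
    class = "tcvs_fit")
}

#' Constrained OLS refit on a selected set
#'
#' Least-squares fit of `y` on the selected CLR columns under the zero-sum
#' constraint on the coefficients, solved in closed form via the KKT system.
#' With one or zero columns the constraint forces all coefficients to zero.
#'
#' @param y Response vector.
#' @param z_s CLR columns of the selected taxa (n x |S|).
#' @param intercept Include an intercept by centering (default `TRUE`).
#' @return Numeric coefficient vector (attribute `intercept`), summing to 0.
#' @export
constrained_ols_refit <- function(y, z_s, intercept = TRUE) {
  z_s <- as.matrix(z_s)
  n <- nrow(z_s)
  k <- ncol(z_s)
  ybar <- if (intercept) mean(y) else 0
  if (k <= 1) {
    if (k == 1) warn("single selected column: zero-sum constraint forces 0")
    out <- rep(0, k)
    attr(out, "intercept") <- ybar
    return(out)
  }
  zc <- if (intercept) scale(z_s, center = TRUE, scale = FALSE) else z_s
  yc <- y - ybar
  q <- crossprod(zc) / n
  kkt <- rbind(cbind(q, rep(1, k)), c(rep(1, k), 0))
  rhs <- c(crossprod(zc, yc) / n, 0)
  sol <- tryCatch(solve(kkt, rhs), error = function(e) {
    warn("singular refit system; ridge-stabilizing with 1e-8")
    solve(kkt + diag(1e-8, k + 1), rhs)
  })
  b <- sol[seq_len(k)]
  b <- b - mean(b)  # exact constraint under numerical noise
  attr(b, "intercept") <- if (intercept) {
    ybar - sum(colMeans(z_s) * b)
  } else 0
  b
}

#' @export
print.tcvs_fit <- function(x, ...) {
  cat(sprintf("constrained sparse group lasso fit (lambda = %.4g)\n", x$lambda))
  cat(sprintf("  nonzero: %d of %d original%s; converged: %s (%d iterations)\n",
              sum(x$beta != 0), x$p,
              if (x$has_knockoffs)
                sprintf(", %d of %d knockoff", sum(x$beta_tilde != 0), x$p)
              else "",
              x$converged, x$iterations))
  invisible(x)
}

#' Tidy a penalized fit
#'
#' @param x A `tcvs_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `type`
#'   (original / knockoff / covariate), `estimate`.
#' @method tidy tcvs_fit
#' @export
tidy.tcvs_fit <- function(x, ...) {
  terms <- names(x$beta) %||% paste0("taxon", seq_along(x$beta))
  out <- tibble::tibble(term = terms, type = "original",
                        estimate = unname(x$beta))
  if (!is.null(x$beta_tilde)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = paste0(terms, "_knockoff"), type = "knockoff",
      estimate = x$beta_tilde))
  }
  if (!is.null(x$gamma)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = names(x$gamma) %||% paste0("covariate", seq_along(x$gamma)),
      type = "covariate", estimate = unname(x$gamma)))
  }
  out
}

#' Fit-level summary
#'
#' @param x A `tcvs_fit`.
#' @param ... Unused.
#' @return A one-row tibble: lambda, objective, support sizes, convergence.
#' @method glance tcvs_fit
#' @export
glance.tcvs_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, objective = x$objective,
                 df = sum(x$beta != 0) +
                   if (is.null(x$beta_tilde)) 0L else sum(x$beta_tilde != 0),
                 converged = x$converged, iterations = x$iterations,
                 constraint_violation = x$constraint_violation)
}
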
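#' Fit a Gaussian model to CLR data with covariance shrinkage
#'
#' Estimates the mean and covariance used for model-X knockoff construction.
#' CLR rows sum to zero, so the empirical covariance is exactly singular;
#' the estimate is therefore shrunk toward a scaled identity
#' `(1 - gamma) S + gamma m I` (`m` = mean diagonal of `S`). With
#' `shrinkage = "auto"` the intensity is a Ledoit-Wolf-type analytic value,
#' floored so the smallest eigenvalue is at least `1e-8 * m`.
#'
#' @param z Numeric matrix (n x p) of CLR coordinates, `n >= 2`.
#' @param shrinkage `"auto"` or a fixed intensity in `[0, 1]`.
#' @return A `gaussian_model`: `mu`, `sigma`, `shrinkage_intensity`.
#' @export
fit_gaussian <- function(z, shrinkage = "auto") {
  z <- as_numeric_matrix(z, "z")
  n <- nrow(z)
  p <- ncol(z)
  if (n < 2) abort("need at least 2 samples to estimate a covariance")
  if (any(apply(z, 2, stats::sd) == 0)) {
    warn("constant column in z; covariance is rank deficient")
  }
  mu <- colMeans(z)
  zc <- sweep(z, 2, mu, "-")
  s <- crossprod(zc) / (n - 1)
  m <- mean(diag(s))
  if (m <= 0) abort("degenerate data: zero average variance")

  if (identical(shrinkage, "auto")) {
    # Ledoit-Wolf intensity toward the scaled-identity target
    d2 <- sum((s - diag(m, p))^2)
    b2 <- 0
    for (i in seq_len(n)) {
      b2 <- b2 + sum((tcrossprod(zc[i, ]) - s)^2)
    }
    b2 <- min(b2 / n^2, d2)
    gamma <- if (d2 > 0) b2 / d2 else 1
  } else {
    gamma <- as.numeric(shrinkage)
    if (gamma < 0 || gamma > 1) abort("shrinkage must lie in [0, 1]")
  }
  # floor: eigmin((1-g)S + g m I) = (1-g) eigmin(S) + g m >= 1e-8 m
  emin <- min(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
  floor_val <- 1e-8 * m
  if ((1 - gamma) * emin + gamma * m < floor_val) {
    gamma <- max(gamma, (floor_val - emin) / (m - emin))
  }
  sigma <- (1 - gamma) * s + gamma * m * diag(p)
  sigma <- (sigma + t(sigma)) / 2
  structure(list(mu = mu, sigma = sigma, shrinkage_intensity = gamma),
            class = "gaussian_model")
}

#' Solve for the knockoff decorrelation vector s
#'
#' Finds `s >= 0` with `2 Sigma - diag(s)` positive semidefinite; larger `s`
#' decorrelates each variable more from its knockoff. `"equi"` uses the
#' equicorrelated closed form `s_j = min(2 lambda_min(R), 1) * sigma_jj` on
#' the correlation scale. `"sdp"` maximizes `sum(s)` under the same
#' feasibility constraint by cyclic coordinate ascent (each coordinate
#' maximum via a Schur complement), starting from the equicorrelated point.
#'
#' @param model A `gaussian_model`.
#' @param method `"equi"` (default) or `"sdp"`.
#' @return Numeric vector `s` with `eigmin(2 Sigma - diag(s)) >= -1e-10`.
#' @export
solve_s <- function(model, method = c("equi", "sdp")) {
  method <- match.arg(method)
  sigma <- model$sigma
  p <- ncol(sigma)
  dsd <- sqrt(diag(sigma))
  corr <- sigma / tcrossprod(dsd)
  emin <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  s_corr <- rep(min(2 * emin, 1), p)

  if (method == "sdp") {
    s_try <- tryCatch({
      sc <- pmin(0.5 * s_corr, 1)
      for (sweep_i in 1:6) {
        b <- 2 * corr - diag(sc, p)
        binv <- solve(b)
        for (j in seq_len(p)) {
          # largest increase of sc_j keeping b PSD (Schur complement)
          room <- 1 / binv[j, j]
          new_j <- min(sc[j] + 0.95 * room, 1)
          delta <- new_j - sc[j]
          if (delta > 1e-12 && delta * binv[j, j] < 0.999) {
            # rank-one downdate of the inverse (Sherman-Morrison)
            bj <- binv[, j]
            binv <- binv + (delta / (1 - delta * binv[j, j])) * tcrossprod(bj)
            sc[j] <- new_j
          }
        }
      }
      # pull back to strict feasibility if rounding overshot
      for (k in 1:20) {
        emin <- min(eigen(2 * corr - diag(sc, p), symmetric = TRUE,
                          only.values = TRUE)$values)
        if (emin >= -1e-12) break
        sc <- sc * 0.999
      }
      sc
    }, error = function(e) NULL)
    if (is.null(s_try) ||
        min(eigen(2 * corr - diag(s_try, p), symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-10) {
      warn("sdp coordinate ascent infeasible; falling back to equicorrelated")
    } else if (sum(s_try) > sum(pmin(s_corr, 1))) {
      # ascent is order-dependent: keep whichever feasible point has the
      # larger total decorrelation
      s_corr <- s_try
    }
  }
  s <- pmax(s_corr, 0) * dsd^2
  feas <- min(eigen(2 * sigma - diag(s, p), symmetric = TRUE,
                    only.values = TRUE)$values)
  if (feas < -1e-10) {
    # numerically safe pullback
    s <- s * (1 - 1e-8)
  }
  s
}

#' Sample Gaussian model-X knockoffs
#'
#' Draws knockoff rows from the conditional law
#' `Z~_i | Z_i ~ N(Z_i - diag(s) Sigma^{-1} (Z_i - mu),
#' 2 diag(s) - diag(s) Sigma^{-1} diag(s))`, the closed form of the
#' sequential conditional independent pairs construction for a multivariate
#' normal. The draw is deterministic given `seed`; `Z` is never modified.
#'
#' @param z CLR matrix (n x p).
#' @param model A `gaussian_model` fitted to `z`.
#' @param s Decorrelation vector from [solve_s()].
#' @param seed Integer seed controlling the knockoff noise.
#' @return Numeric matrix of the same shape as `z`.
#' @export
sample_knockoffs <- function(z, model, s, seed = 1) {
  z <- as_numeric_matrix(z, "z")
  p <- ncol(z)
  sig_inv_s <- solve(model$sigma, diag(s, p))
  mean_mat <- z - sweep(z, 2, model$mu, "-") %*% sig_inv_s
  cond_cov <- 2 * diag(s, p) - diag(s, p) %*% sig_inv_s
  cond_cov <- (cond_cov + t(cond_cov)) / 2
  ee <- eigen(cond_cov, symmetric = TRUE)
  if (min(ee$values) < -1e-8 * max(abs(ee$values), 1)) {
    warn("conditional covariance not PSD; clipping negative eigenvalues")
  }
  half <- ee$vectors %*% (sqrt(pmax(ee$values, 0)) * t(ee$vectors))
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  noise <- matrix(rnorm(nrow(z) * p), nrow(z), p)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  zt <- mean_mat + noise %*% half
  dimnames(zt) <- dimnames(z)
  zt
}

#' Construct a knockoff copy of a CLR matrix
#'
#' Convenience wrapper: fit the Gaussian model, solve for `s`, and sample.
#'
#' @inheritParams sample_knockoffs
#' @inheritParams solve_s
#' @inheritParams fit_gaussian
#' @return A `knockoff_set`: `z_tilde`, `s`, `model`, `method`, `seed`.
#' @export
create_knockoffs <- function(z, method = c("equi", "sdp"), seed = 1,
                             shrinkage = "auto") {
  method <- match.arg(method)
  model <- fit_gaussian(z, shrinkage = shrinkage)
  s <- solve_s(model, method = method)
  zt <- sample_knockoffs(z, model, s, seed = seed)
  structure(list(z_tilde = zt, s = s, model = model, method = method,
                 seed = seed),
            class = "knockoff_set")
}

#' @export
print.knockoff_set <- function(x, ...) {
  cat(sprintf("knockoff set: %d x %d (%s, seed %d, shrinkage %.3g)\n",
              nrow(x$z_tilde), ncol(x$z_tilde), x$method, x$seed,
              x$model$shrinkage_intensity))
  invisible(x)
}
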
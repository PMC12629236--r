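#' True coefficient vectors of the two benchmark settings
#'
#' Setting I places 12 nonzero coefficients on taxa clustered on the
#' simulation tree ({1,2,4,5,8,9,10,11,12,18,19,20}); Setting II scatters 12
#' nonzero coefficients across the tree (largest index 53). Both vectors sum
#' to zero, consistent with the CLR model's identifiability constraint, and
#' keep exactly 12 nonzeros regardless of `p`.
#'
#' @param setting `"I"` or `"II"`.
#' @param p Number of taxa (at least 60).
#' @return Numeric vector of length `p`.
#' @export
setting_coefficients <- function(setting = c("I", "II"), p = 60) {
  setting <- match.arg(setting)
  if (p < 60) abort("settings are defined for p >= 60")
  beta <- numeric(p)
  if (setting == "I") {
    idx <- c(1, 2, 4, 5, 8, 9, 10, 11, 12, 18, 19, 20)
    val <- c(1, -1, 0.8, -0.8, -1.5, -0.5, 2, 1.2, -1.2, 0.7, 0.8, -1.5)
  } else {
    idx <- c(1, 8, 16, 26, 29, 34, 41, 44, 47, 49, 51, 53)
    val <- c(-0.5, 2, -1.3, 0.5, 1.3, -2, 0.8, -0.4, -1.6, -1.3, 1.3, 1.2)
  }
  beta[idx] <- val
  stopifnot(abs(sum(beta)) < 1e-12, sum(beta != 0) == 12)
  beta
}

#' Synthetic Dirichlet-Multinomial parameters
#'
#' A download-free stand-in for DM parameters fitted to a real 16S count
#' table: mean proportions are log-normally dispersed (heavy-tailed,
#' microbiome-like rank-abundance), overdispersion 0.02, and per-sample
#' sequencing depths uniform on [5000, 10000]. Deterministic given `seed`.
#'
#' @param p Number of taxa (>= 2).
#' @param seed Integer seed.
#' @param overdispersion DM overdispersion theta in (0, 1).
#' @return A `dm_parameters` object: `proportions` (sums to 1),
#'   `overdispersion`, `depth_range`.
#' @export
synthetic_dm_parameters <- function(p, seed = 1, overdispersion = 0.02) {
  if (p < 2) abort("p must be at least 2")
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  raw <- exp(rnorm(p, mean = 0, sd = 2))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  new_dm_parameters(raw / sum(raw), overdispersion, c(5000, 10000))
}

new_dm_parameters <- function(proportions, overdispersion, depth_range) {
  stopifnot(all(proportions > 0), abs(sum(proportions) - 1) < 1e-10,
            overdispersion > 0, overdispersion < 1)
  structure(list(proportions = proportions,
                 overdispersion = overdispersion,
                 depth_range = depth_range),
            class = "dm_parameters")
}

#' Method-of-moments Dirichlet-Multinomial estimation
#'
#' Estimates mean proportions as pooled column proportions and the
#' overdispersion theta by the moment (Weir-type) estimator comparing
#' between-sample to within-sample mean squares.
#'
#' @param counts Count matrix (samples x taxa).
#' @param depth_range Depth range to record for simulation (defaults to the
#'   observed depth range).
#' @return A `dm_parameters` object.
#' @export
estimate_dm_parameters <- function(counts, depth_range = NULL) {
  counts <- as_numeric_matrix(counts, "counts")
  validate_counts(counts)
  n <- nrow(counts)
  if (n < 2) abort("need at least 2 samples")
  depths <- rowSums(counts)
  if (any(depths == 0)) abort("sample with zero total count")
  pi_hat <- colSums(counts) / sum(counts)
  if (any(pi_hat == 0)) {
    # taxa never observed: give them the smallest representable share
    pi_hat <- (colSums(counts) + 0.5) / sum(colSums(counts) + 0.5)
  }
  props <- counts / depths
  dev <- sweep(props, 2, colSums(counts) / sum(counts), "-")
  msp <- sum(depths * rowSums(dev^2)) / (n - 1)
  msg <- sum(rowSums(props * (1 - props)) * depths) / (sum(depths) - n)
  nc <- (sum(depths) - sum(depths^2) / sum(depths)) / (n - 1)
  theta <- (msp - msg) / (msp + (nc - 1) * msg)
  theta <- min(max(theta, 1e-8), 0.99)
  new_dm_parameters(pi_hat, theta, depth_range %||% range(depths))
}

#' Deterministic laminar tree for the simulation benchmarks
#'
#' Builds the synthetic taxonomic tree used by the simulation settings. The
#' benchmark's Setting I is the signals-on-the-tree regime: its 12 signal
#' taxa {1,2,4,5,8,9,10,11,12,18,19,20} occupy *whole* genus-level subtrees,
#' so for `p >= 60` the first 20 leaves are partitioned into genera that
#' respect that signal set ({1,2}, {3}, {4,5}, {6,7}, {8,...,12},
#' {13,...,17}, {18,19,20}) while the remaining leaves form uniform genus
#' blocks of `genus_size`. Setting II scatters its signals without regard to
#' these nodes. Genera are grouped `genera_per_family` at a time into
#' families under a single root. This is a synthetic stand-in topology, not
#' a real taxonomy.
#'
#' @param p Number of leaves.
#' @param genus_size Leaves per uniform genus block (default 4).
#' @param genera_per_family Genus blocks per family (default 3).
#' @return A `taxonomic_tree` with leaves `taxon1 ... taxonp`.
#' @export
simulation_tree <- function(p, genus_size = 4, genera_per_family = 3) {
  taxa <- paste0("taxon", seq_len(p))
  genus_id <- integer(p)
  if (p >= 60) {
    head_blocks <- list(1:2, 3L, 4:5, 6:7, 8:12, 13:17, 18:20)
    for (i in seq_along(head_blocks)) genus_id[head_blocks[[i]]] <- i
    rest <- 21:p
    genus_id[rest] <- length(head_blocks) +
      (rest - 21L) %/% genus_size + 1L
  } else {
    genus_id <- (seq_len(p) - 1L) %/% genus_size + 1L
  }
  family_id <- (genus_id - 1L) %/% genera_per_family + 1L
  taxonomy_tree(data.frame(taxon = taxa,
                           Family = paste0("f", family_id),
                           Genus = paste0("g", genus_id),
                           stringsAsFactors = FALSE))
}

#' Simulate a benchmark dataset
#'
#' Draws Dirichlet-Multinomial counts at the given parameters, closes them
#' with a 0.5 pseudo-count, applies the CLR transform, and generates the
#' response `y = Z beta + eps` with `eps ~ N(0, noise_sd^2)`. The true
#' coefficients are the chosen setting's vector scaled by `shrinkage`.
#'
#' @param params A `dm_parameters` object.
#' @param n Sample size (default 200).
#' @param setting `"I"` or `"II"` (ignored when `beta` is given).
#' @param shrinkage Effect-size multiplier in (0, 1] (default 1).
#' @param noise_sd Residual standard deviation (default 1).
#' @param seed Integer seed.
#' @param beta Optional explicit true coefficient vector (length p).
#' @param pseudo_count Closure pseudo-count (default 0.5).
#' @return A list: `counts`, `x` (compositions), `z` (CLR), `y`, `beta`.
#' @export
simulate_dataset <- function(params, n = 200, setting = "I", shrinkage = 1,
                             noise_sd = 1, seed = 1, beta = NULL,
                             pseudo_count = 0.5) {
  stopifnot(inherits(params, "dm_parameters"))
  p <- length(params$proportions)
  if (is.null(beta)) beta <- setting_coefficients(setting, p) * shrinkage
  if (length(beta) != p) abort("beta length does not match p")
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  depths <- round(runif(n, params$depth_range[1], params$depth_range[2]))
  alpha <- params$proportions *
    (1 - params$overdispersion) / params$overdispersion
  counts <- matrix(0, n, p, dimnames = list(paste0("sample", seq_len(n)),
                                            paste0("taxon", seq_len(p))))
  for (i in seq_len(n)) {
    g <- rgamma(p, shape = alpha)
    pr <- g / sum(g)
    counts[i, ] <- stats::rmultinom(1, depths[i], pr)
  }
  x <- close_counts(counts, pseudo_count)
  z <- clr_transform(x)
  y <- as.numeric(z %*% beta) + noise_sd * rnorm(n)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  list(counts = counts, x = x, z = z, y = y, beta = beta)
}

#' Selection error rates against a true coefficient vector
#'
#' `TPR` is the fraction of true-support taxa selected; `FPR` the fraction
#' of null taxa selected.
#'
#' @param selected Integer indices of selected taxa.
#' @param beta_true True coefficient vector.
#' @return A named list with `tpr` and `fpr`.
#' @export
tpr_fpr <- function(selected, beta_true) {
  truth <- which(beta_true != 0)
  if (length(truth) == 0) abort("empty true support: TPR undefined")
  nulls <- which(beta_true == 0)
  list(tpr = length(intersect(selected, truth)) / length(truth),
       fpr = if (length(nulls) == 0) 0
             else length(intersect(selected, nulls)) / length(nulls))
}

#' F-score of a selection
#'
#' Harmonic mean of precision and recall over the selected vs true supports;
#' 0 when either is zero or undefined (empty selection).
#'
#' @inheritParams tpr_fpr
#' @return The F-score in [0, 1].
#' @export
f_score <- function(selected, beta_true) {
  truth <- which(beta_true != 0)
  if (length(selected) == 0 || length(truth) == 0) return(0)
  tp <- length(intersect(selected, truth))
  prec <- tp / length(selected)
  rec <- tp / length(truth)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

run_variant_safely <- function(variant, sim, tree, q, seed, nlambda, control) {
  tryCatch({
    sel <- run_tcvs(sim$counts, tree = tree, y = sim$y, variant = variant,
                    q = q, seed = seed, nlambda = nlambda, control = control)
    rates <- tpr_fpr(sel$selected, sim$beta)
    tibble::tibble(variant = variant, tpr = rates$tpr, fpr = rates$fpr,
                   f_score = f_score(sel$selected, sim$beta),
                   n_selected = length(sel$selected), failed = FALSE)
  }, error = function(e) {
    tibble::tibble(variant = variant, tpr = NA_real_, fpr = NA_real_,
                   f_score = NA_real_, n_selected = NA_integer_,
                   failed = TRUE)
  })
}

#' Replicate benchmark of the selection methods
#'
#' Repeats the simulation protocol — DM counts, CLR, response from the
#' chosen setting — and runs each requested method, reporting per-replicate
#' and mean TPR/FPR/F-score. Failed replicates are recorded as `NA` and
#' excluded from means. The master seed deterministically spawns one seed
#' per replicate.
#'
#' @param methods Subset of `c("tcvs", "tlasso", "classokf", "classo")`.
#' @param setting `"I"` or `"II"`.
#' @param p Number of taxa (default 60).
#' @param n Sample size (default 200).
#' @param replicates Number of simulation replicates.
#' @param seed Master seed.
#' @param q Knockoff level (default 0.05).
#' @param shrinkage Effect-size multiplier (default 1).
#' @param params Optional `dm_parameters`; defaults to
#'   [synthetic_dm_parameters()] at this `p`.
#' @param tree Optional `taxonomic_tree`; defaults to [simulation_tree()].
#' @param nlambda Lambda grid length per fit.
#' @param control Solver control list.
#' @return A `tcvs_benchmark`: `replicates` tibble (one row per replicate
#'   and method) and `summary` tibble of means.
#' @export
run_benchmark <- function(methods = c("tcvs", "tlasso", "classokf", "classo"),
                          setting = "I", p = 60, n = 200, replicates = 20,
                          seed = 1, q = 0.05, shrinkage = 1, params = NULL,
                          tree = NULL, nlambda = 50, control = list()) {
  methods <- match.arg(methods, c("tcvs", "tlasso", "classokf", "classo"),
                       several.ok = TRUE)
  params <- params %||% synthetic_dm_parameters(p, seed = 20260101)
  tree <- tree %||% simulation_tree(p)
  seeds <- derive_seeds(seed, replicates)
  rows <- purrr::map_dfr(seq_len(replicates), function(r) {
    sim <- simulate_dataset(params, n = n, setting = setting,
                            shrinkage = shrinkage, seed = seeds[r])
    purrr::map_dfr(methods, function(m) {
      dplyr::mutate(run_variant_safely(m, sim, tree, q, seeds[r], nlambda,
                                       control),
                    replicate = r, seed = seeds[r], .before = 1)
    })
  })
  summ <- rows |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(tpr = mean(.data$tpr, na.rm = TRUE),
                     fpr = mean(.data$fpr, na.rm = TRUE),
                     f_score = mean(.data$f_score, na.rm = TRUE),
                     n_failed = sum(.data$failed), .groups = "drop")
  structure(list(replicates = rows, summary = summ, setting = setting,
                 p = p, n = n, q = q, shrinkage = shrinkage, seed = seed),
            class = "tcvs_benchmark")
}

#' @export
print.tcvs_benchmark <- function(x, ...) {
  cat(sprintf("benchmark: setting %s, p = %d, n = %d, %d replicates\n",
              x$setting, x$p, x$n, max(x$replicates$replicate)))
  print(x$summary)
  invisible(x)
}

#' @method tidy tcvs_benchmark
#' @export
tidy.tcvs_benchmark <- function(x, ...) x$replicates

#' @method glance tcvs_benchmark
#' @export
glance.tcvs_benchmark <- function(x, ...) {
  dplyr::mutate(x$summary, setting = x$setting, p = x$p, n = x$n,
                shrinkage = x$shrinkage)
}

#' Effect-size sweep of mean F-scores
#'
#' Runs the benchmark across a grid of effect-size shrinkage factors
#' (default nine equally spaced points from 0.2 to 1, 20 replicates each)
#' and reports the mean F-score per method and factor.
#'
#' @inheritParams run_benchmark
#' @param factors Shrinkage factors (default `seq(0.2, 1, length.out = 9)`).
#' @return A `tcvs_sweep` with a tibble of mean F-scores.
#' @export
shrinkage_sweep <- function(methods = c("tcvs", "tlasso", "classokf", "classo"),
                            setting = "I", p = 60, n = 200, replicates = 20,
                            factors = seq(0.2, 1, length.out = 9), seed = 1,
                            q = 0.05, params = NULL, tree = NULL,
                            nlambda = 50, control = list()) {
  res <- purrr::map_dfr(seq_along(factors), function(i) {
    bench <- run_benchmark(methods = methods, setting = setting, p = p,
                           n = n, replicates = replicates, seed = seed + i,
                           q = q, shrinkage = factors[i], params = params,
                           tree = tree, nlambda = nlambda, control = control)
    dplyr::mutate(bench$summary, shrinkage = factors[i], .before = 1)
  })
  structure(list(results = res, setting = setting, p = p, n = n,
                 replicates = replicates, seed = seed),
            class = "tcvs_sweep")
}

#' @export
print.tcvs_sweep <- function(x, ...) {
  cat(sprintf("effect-size sweep: setting %s, p = %d, %d replicates/point\n",
              x$setting, x$p, x$replicates))
  print(tidyr::pivot_wider(x$results[, c("shrinkage", "variant", "f_score")],
                           names_from = "variant", values_from = "f_score"))
  invisible(x)
}

#' @method tidy tcvs_sweep
#' @export
tidy.tcvs_sweep <- function(x, ...) x$results

#' Plot an effect-size sweep
#'
#' @param object A `tcvs_sweep`.
#' @param ... Unused.
#' @return A ggplot of mean F-score against the shrinkage factor per method.
#' @method autoplot tcvs_sweep
#' @export
autoplot.tcvs_sweep <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$shrinkage, y = .data$f_score,
                               colour = .data$variant)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "effect-size shrinkage factor", y = "mean F-score",
                  colour = "method") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Bootstrap resampling evaluation with constrained OLS refits
#'
#' The half-sample protocol for comparing selection methods on a real
#' dataset: each replicate draws a training half (without replacement),
#' fits each method on it, then scores prediction on the held-out half. For
#' penalty-only methods (`tlasso`, `classo`) the training coefficients are
#' used directly: `MSPE = ||y2 - Z2 beta1||^2 / n2`. For knockoff methods
#' (`tcvs`, `classokf`) the held-out half is split 80/20: a constrained OLS
#' refit on the selected set uses the 80%, and the MSPE is computed on the
#' 20%. Per-taxon selection frequencies are reported with the set of taxa
#' selected in at least `freq_threshold` of replicates; an empty selection
#' falls back to an intercept-only prediction and is flagged.
#'
#' @inheritParams run_tcvs
#' @param methods Methods to evaluate.
#' @param n_boot Number of resampling replicates (default 100).
#' @param freq_threshold Selection-frequency cutoff (default 0.1).
#' @param seed Master seed.
#' @param nlambda Lambda grid length per fit.
#' @param control Solver control list.
#' @return A `tcvs_bootstrap`: per-replicate MSPE tibble, per-taxon
#'   selection frequencies, the frequency-filtered taxon sets, and a
#'   summary (mean MSPE with standard errors and filtered counts).
#' @export
bootstrap_evaluate <- function(counts, tree = NULL, y, covariates = NULL,
                               methods = c("tcvs", "tlasso", "classokf",
                                           "classo"),
                               n_boot = 100, freq_threshold = 0.1,
                               q = 0.05, pseudo_count = 0.5, seed = 1,
                               nlambda = 50, control = list()) {
  methods <- match.arg(methods, c("tcvs", "tlasso", "classokf", "classo"),
                       several.ok = TRUE)
  counts <- as_numeric_matrix(counts, "counts")
  n <- nrow(counts)
  p <- ncol(counts)
  taxa <- colnames(counts) %||% paste0("taxon", seq_len(p))
  if (!is.null(covariates)) covariates <- as_numeric_matrix(covariates,
                                                            "covariates")
  seeds <- derive_seeds(seed, n_boot)
  sel_counts <- matrix(0L, length(methods), p,
                       dimnames = list(methods, taxa))
  rows <- vector("list", n_boot * length(methods))
  ri <- 0L
  for (b in seq_len(n_boot)) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    set.seed(seeds[b])
    train <- sort(sample.int(n, floor(n / 2)))
    hold <- setdiff(seq_len(n), train)
    n_hold <- length(hold)
    split80 <- sort(sample(hold, floor(0.8 * n_hold)))
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
    split20 <- setdiff(hold, split80)
    z_all <- clr_transform(close_counts(counts, pseudo_count))
    for (m in methods) {
      ri <- ri + 1L
      row <- tryCatch({
        sel <- run_tcvs(counts[train, , drop = FALSE], tree = tree,
                        y = y[train],
                        covariates = covariates[train, , drop = FALSE],
                        variant = m, q = q, pseudo_count = pseudo_count,
                        seed = seeds[b], nlambda = nlambda, control = control)
        s <- sel$selected
        sel_counts[m, s] <- sel_counts[m, s] + 1L
        if (m %in% c("tlasso", "classo")) {
          yhat <- sel$fit$intercept +
            z_all[hold, , drop = FALSE] %*% sel$fit$beta
          if (!is.null(sel$fit$gamma)) {
            yhat <- yhat +
              covariates[hold, , drop = FALSE] %*% sel$fit$gamma
          }
          mspe <- mean((y[hold] - yhat)^2)
          empty <- length(s) == 0
        } else if (length(s) >= 2) {
          refit <- constrained_ols_refit(y[split80],
                                         z_all[split80, s, drop = FALSE])
          yhat <- attr(refit, "intercept") +
            z_all[split20, s, drop = FALSE] %*% as.numeric(refit)
          mspe <- mean((y[split20] - yhat)^2)
          empty <- FALSE
        } else {
          mspe <- mean((y[split20] - mean(y[split80]))^2)
          empty <- TRUE
        }
        tibble::tibble(replicate = b, variant = m, mspe = mspe,
                       n_selected = length(s), empty_selection = empty,
                       failed = FALSE)
      }, error = function(e) {
        tibble::tibble(replicate = b, variant = m, mspe = NA_real_,
                       n_selected = NA_integer_, empty_selection = NA,
                       failed = TRUE)
      })
      rows[[ri]] <- row
    }
  }
  reps <- dplyr::bind_rows(rows)
  freq <- tibble::as_tibble(sel_counts / n_boot, rownames = "variant") |>
    tidyr::pivot_longer(-"variant", names_to = "taxon",
                        values_to = "frequency")
  filtered <- freq |>
    dplyr::filter(.data$frequency >= freq_threshold) |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(taxa = list(.data$taxon), n_taxa = dplyr::n(),
                     .groups = "drop")
  summ <- reps |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(mean_mspe = mean(.data$mspe, na.rm = TRUE),
                     se_mspe = stats::sd(.data$mspe, na.rm = TRUE) /
                       sqrt(sum(!is.na(.data$mspe))),
                     n_failed = sum(.data$failed), .groups = "drop") |>
    dplyr::left_join(filtered[, c("variant", "n_taxa")], by = "variant") |>
    dplyr::mutate(n_taxa = dplyr::coalesce(.data$n_taxa, 0L))
  structure(list(replicates = reps, frequencies = freq, filtered = filtered,
                 summary = summ, freq_threshold = freq_threshold,
                 n_boot = n_boot, seed = seed),
            class = "tcvs_bootstrap")
}

#' @export
print.tcvs_bootstrap <- function(x, ...) {
  cat(sprintf("bootstrap evaluation: %d replicates, frequency cutoff %g\n",
              x$n_boot, x$freq_threshold))
  print(x$summary)
  invisible(x)
}

#' @method tidy tcvs_bootstrap
#' @export
tidy.tcvs_bootstrap <- function(x, ...) x$frequencies

#' @method glance tcvs_bootstrap
#' @export
glance.tcvs_bootstrap <- function(x, ...) x$summary
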
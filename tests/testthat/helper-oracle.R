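`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent convex oracle for the constrained sparse group lasso, used to
# check the ADMM solver and the hierarchical prox. Majorize-minimize on an
# epsilon-smoothed objective:
#   |b|            <= (b^2 / m + m) / 2            at m = sqrt(b_k^2 + eps)
#   ||b_g||        <= (||b_g||^2 / m + m) / 2      at m = sqrt(||b_g||^2 + eps)
# Each MM step is an equality-constrained ridge problem solved by its KKT
# system; eps is annealed. This shares no code with the ADMM/prox path.
oracle_solve <- function(y, design, groups = list(), group_w = numeric(0),
                         l1w = NULL, blocks = list(), lambda, n = NULL,
                         iters = 400, eps_seq = 10^seq(-2, -14, length.out = 60)) {
  design <- as.matrix(design)
  n <- n %||% nrow(design)
  d <- ncol(design)
  if (is.null(l1w)) l1w <- rep(1, d)
  q <- crossprod(design) / n
  r <- crossprod(design, y) / n
  k <- length(blocks)
  a <- matrix(0, k, d)
  for (i in seq_len(k)) a[i, blocks[[i]]] <- 1
  b <- rep(0, d)
  for (eps in eps_seq) {
    for (it in 1:40) {
      wdiag <- lambda * l1w / sqrt(b^2 + eps)
      for (g in seq_along(groups)) {
        idx <- groups[[g]]
        m <- sqrt(sum(b[idx]^2) + eps)
        wdiag[idx] <- wdiag[idx] + lambda / (group_w[g] * m)
      }
      h <- q + diag(wdiag, d)
      kkt <- if (k > 0) rbind(cbind(h, t(a)), cbind(a, matrix(0, k, k)))
             else h
      rhs <- c(r, rep(0, k))
      sol <- solve(kkt, rhs)
      b_new <- sol[seq_len(d)]
      if (max(abs(b_new - b)) < 1e-13) { b <- b_new; break }
      b <- b_new
    }
  }
  obj <- oracle_objective(y, design, b, groups, group_w, l1w, lambda, n = n)
  list(coefficients = b, objective = obj)
}

oracle_objective <- function(y, design, b, groups = list(),
                             group_w = numeric(0), l1w = NULL, lambda,
                             n = NULL) {
  design <- as.matrix(design)
  n <- n %||% nrow(design)
  if (is.null(l1w)) l1w <- rep(1, ncol(design))
  pen <- sum(l1w * abs(b))
  for (g in seq_along(groups)) {
    pen <- pen + sqrt(sum(b[groups[[g]]]^2)) / group_w[g]
  }
  sum((y - design %*% b)^2) / (2 * n) + lambda * pen
}

# Prox problem as a special case: 0.5||b - u||^2 + tau * penalty is the
# lambda = tau, design = I, n = 1 instance of the same oracle.
oracle_prox <- function(u, groups = list(), group_w = numeric(0),
                        l1w = NULL, tau) {
  oracle_solve(u, diag(length(u)), groups, group_w, l1w,
               blocks = list(), lambda = tau, n = 1)
}

# Brute-force knockoff threshold: evaluate the ratio at every candidate.
brute_force_threshold <- function(w, q, plus = FALSE) {
  cand <- sort(unique(abs(w[w != 0])))
  ok <- vapply(cand, function(t) {
    (sum(w <= -t) + if (plus) 1 else 0) / max(1, sum(w >= t)) <= q
  }, logical(1))
  if (any(ok)) min(cand[ok]) else Inf
}

# Random laminar group structure over p coordinates for property tests:
# contiguous blocks plus the root, as a tcvs_groups-compatible list.
random_laminar_groups <- function(p, n_internal = 2) {
  cuts <- sort(unique(c(0, sample(seq_len(p - 1), min(n_internal, p - 1)), p)))
  members <- lapply(seq_len(length(cuts) - 1),
                    function(i) seq(cuts[i] + 1, cuts[i + 1]))
  members <- c(members, list(seq_len(p)))
  keys <- vapply(members, paste, character(1), collapse = ",")
  members <- members[!duplicated(keys)]
  structure(list(p = p,
                 ids = paste0("g", seq_along(members)),
                 ranks = rep("synthetic", length(members)),
                 members = lapply(members, as.integer),
                 weights = lengths(members),
                 augmented = FALSE),
            class = "tcvs_groups")
}
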
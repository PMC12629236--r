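random_regression <- function(p = 5, n = 50, seed = 1) {
  set.seed(seed)
  z <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  beta <- beta - mean(beta)
  y <- as.numeric(z %*% beta) + rnorm(n)
  list(z = z, y = y)
}

test_that("objective evaluation matches the independent oracle formulation", {
  dat <- random_regression(5, 40, seed = 101)
  gs <- random_laminar_groups(5, 2)
  set.seed(102)
  b <- rnorm(5)
  lam <- 0.2
  expect_equal(tcvs_objective(dat$y, dat$z, b, gs, lam),
               oracle_objective(dat$y, dat$z, b, gs$members, gs$weights,
                                lambda = lam),
               tolerance = 1e-9)
  # lambda = 0: pure least squares; zero coefficients: half mean square of y
  expect_equal(tcvs_objective(dat$y, dat$z, b, gs, 0),
               sum((dat$y - dat$z %*% b)^2) / (2 * 40))
  expect_equal(tcvs_objective(dat$y, dat$z, rep(0, 5), gs, lam),
               sum(dat$y^2) / (2 * 40))
  expect_error(tcvs_objective(dat$y, dat$z, rnorm(4), gs, lam), "mismatch")
})

test_that("hierarchical prox handles fixed points and singletons exactly", {
  gs <- random_laminar_groups(4, 1)
  expect_equal(hierarchical_prox(rep(0, 4), gs, 0.3), rep(0, 4))
  # single leaf under a singleton group: two sequential shrinkages
  gs1 <- structure(list(p = 1, ids = "g", ranks = "r",
                        members = list(1L), weights = 1, augmented = FALSE),
                   class = "tcvs_groups")
  got <- hierarchical_prox(1, gs1, 0.3)
  grid <- seq(-1.5, 1.5, by = 1e-5)
  objs <- 0.5 * (grid - 1)^2 + 0.3 * (abs(grid) + abs(grid))
  expect_equal(got, grid[which.min(objs)], tolerance = 1e-4)
  expect_error(hierarchical_prox(1, gs1, -1), "non-negative")
})

test_that("prox composition equals the convex oracle on small laminar trees", {
  set.seed(103)
  for (rep in 1:10) {
    p <- sample(3:5, 1)
    gs <- random_laminar_groups(p, 2)
    u <- rnorm(p, sd = 2)
    tau <- runif(1, 0.1, 0.6)
    mine <- hierarchical_prox(u, gs, tau)
    orc <- oracle_prox(u, gs$members, gs$weights, tau = tau)
    expect_equal(oracle_objective(u, diag(p), mine, gs$members, gs$weights,
                                  lambda = tau, n = 1),
                 orc$objective, tolerance = 1e-6)
  }
})

test_that("full shrinkage at lambda_max returns the null model", {
  dat <- random_regression(6, 50, seed = 104)
  gs <- random_laminar_groups(6, 2)
  lmax <- lambda_max(dat$y, dat$z)
  fit <- tcvs_fit(dat$y, dat$z, gs = gs, lambda = lmax)
  expect_equal(unname(fit$beta), rep(0, 6))
  kn <- create_knockoffs(dat$z, seed = 1)
  fit2 <- tcvs_fit(dat$y, dat$z, z_tilde = kn$z_tilde,
                   gs = augment_groups(gs),
                   lambda = lambda_max(dat$y, dat$z, kn$z_tilde))
  expect_equal(unname(fit2$beta), rep(0, 6))
  expect_equal(fit2$beta_tilde, rep(0, 6))
  expect_error(tcvs_fit(dat$y, dat$z, gs = gs, lambda = -1), "non-negative")
})

test_that("with no penalty, groups or constraint the fit is ordinary least squares", {
  dat <- random_regression(4, 30, seed = 105)
  fit <- tcvs_fit(dat$y, dat$z, lambda = 0, constrain = FALSE,
                  control = list(zero_tol = 0, abstol = 1e-12,
                                 reltol = 1e-11))
  ols <- lm(dat$y ~ dat$z)
  expect_equal(unname(fit$beta), unname(coef(ols)[-1]), tolerance = 1e-8)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-8)
})

test_that("the constrained-lasso reduction matches the convex oracle", {
  dat <- random_regression(6, 50, seed = 106)
  lam <- 0.1
  fit <- tcvs_fit(dat$y, dat$z, lambda = lam)   # no groups: plain CLasso
  zc <- scale(dat$z, center = TRUE, scale = FALSE)
  yc <- dat$y - mean(dat$y)
  orc <- oracle_solve(yc, zc, blocks = list(1:6), lambda = lam)
  expect_equal(tcvs_objective(yc, zc, fit$beta, NULL, lam), orc$objective,
               tolerance = 1e-6)
  expect_lt(abs(sum(fit$beta)), 1e-10)
})

test_that("objective traces descend and optima are monotone in lambda", {
  dat <- random_regression(5, 40, seed = 107)
  gs <- random_laminar_groups(5, 2)
  lmax <- lambda_max(dat$y, dat$z)
  objs <- c()
  for (lam in lmax * c(0.05, 0.2, 0.5, 1)) {
    fit <- tcvs_fit(dat$y, dat$z, gs = gs, lambda = lam)
    tr <- fit$objective_trace
    expect_gte(length(tr), 1)
    # ADMM descent: the trace ends at its minimum and never rises above its
    # starting value
    expect_lte(tr[length(tr)], min(tr) + 1e-8)
    expect_lte(tr[length(tr)], tr[1] + 1e-10)
    objs <- c(objs, fit$objective)
  }
  expect_true(all(diff(objs) > -1e-9))  # optimum non-decreasing in lambda
})

test_that("unpenalized covariates are fitted outside the constraint", {
  set.seed(108)
  z <- matrix(rnorm(300), 60, 5)
  covar <- cbind(fat = rnorm(60), calor = rnorm(60))
  beta <- c(1, -1, 0, 0, 0)
  y <- z %*% beta + covar %*% c(2, -1) + rnorm(60, sd = 0.1)
  fit <- tcvs_fit(y, z, lambda = 0.01, covariates = covar)
  expect_lt(abs(sum(fit$beta)), 1e-10)
  expect_equal(unname(fit$gamma), c(2, -1), tolerance = 0.1)
})

test_that("constrained OLS refit solves the KKT system exactly", {
  set.seed(109)
  z <- matrix(rnorm(100), 50, 2)
  y <- z[, 1] - z[, 2]
  b <- constrained_ols_refit(y, z)
  expect_equal(as.numeric(b), c(1, -1), tolerance = 1e-8)
  # response orthogonal to the columns: coefficients vanish
  y2 <- rnorm(50)
  y2 <- y2 - z %*% solve(crossprod(z), crossprod(z, y2))
  b2 <- constrained_ols_refit(as.numeric(y2), z, intercept = FALSE)
  expect_equal(as.numeric(b2), c(0, 0), tolerance = 1e-8)
  set.seed(110)
  z5 <- matrix(rnorm(250), 50, 5)
  b5 <- constrained_ols_refit(rnorm(50), z5)
  expect_lt(abs(sum(b5)), 1e-10)
  expect_warning(b1 <- constrained_ols_refit(y, z[, 1, drop = FALSE]),
                 "zero-sum")
  expect_equal(as.numeric(b1), 0)
})
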
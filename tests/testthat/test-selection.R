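fake_fit <- function(beta, beta_tilde) {
  structure(list(beta = beta, beta_tilde = beta_tilde, p = length(beta),
                 has_knockoffs = TRUE), class = "tcvs_fit")
}

test_that("knockoff statistics contrast coefficient magnitudes", {
  expect_equal(knockoff_statistics(fake_fit(0.5, 0.2))$w, 0.3)
  expect_equal(knockoff_statistics(fake_fit(c(1, 0), c(0, 2)))$w, c(1, -2))
  expect_equal(knockoff_statistics(fake_fit(-0.4, -0.4))$w, 0)
  stats <- knockoff_statistics(fake_fit(c(1, 0, -2), c(0, 0, 1)))
  expect_equal(stats$nonzero_abs, 1)  # distinct nonzero |w| only
  expect_error(knockoff_statistics(
    structure(list(beta = 1, beta_tilde = NULL), class = "tcvs_fit")),
    "knockoff")
})

test_that("the selection threshold matches hand enumeration", {
  w <- c(2, 3, -1, 4, -2, 5)
  # candidates 1..5; t = 1: 2/4 > 0.25; t = 2: 1/4 <= 0.25
  expect_equal(knockoff_threshold(w, q = 0.25), 2)
  expect_equal(knockoff_threshold(c(0.5, 1, 2), q = 0.1), 0.5)
  expect_equal(knockoff_threshold(c(-1, -2, -3), q = 0.5), Inf)
  expect_equal(knockoff_threshold(rep(0, 6), q = 0.2), Inf)
  expect_error(knockoff_threshold(w, q = 0), "strictly")
})

test_that("the threshold equals brute-force minimization on random statistics", {
  set.seed(201)
  for (rep in 1:120) {
    p <- sample(3:12, 1)
    w <- round(rnorm(p), sample(c(1, 2), 1))
    q <- runif(1, 0.05, 0.6)
    plus <- rep %% 3 == 0
    expect_equal(knockoff_threshold(w, q, plus = plus),
                 brute_force_threshold(w, q, plus = plus))
  }
})

test_that("threshold and selection are monotone in q", {
  set.seed(202)
  w <- rnorm(40)
  qs <- c(0.05, 0.1, 0.2, 0.3, 0.5, 0.7)
  ts <- vapply(qs, function(q) knockoff_threshold(w, q), numeric(1))
  expect_true(all(diff(ts) <= 0))
  sels <- lapply(ts, function(t) which(w >= t))
  for (i in seq_len(length(sels) - 1)) {
    expect_true(all(sels[[i]] %in% sels[[i + 1]]))
  }
})

test_that("BIC follows n log(RSS/n) + df log(n)", {
  # RSS/n = 1, n = 100, 3 nonzero coefficients
  y <- rep(c(1, -1), 50)
  design <- matrix(0, 100, 3)
  expect_equal(bic_score(y, design, c(1, 2, 3)), 3 * log(100))
  expect_equal(bic_score(y, design, c(1, 0, 3)), 2 * log(100))
  # doubling the RSS at fixed support raises BIC by n log 2
  y2 <- sqrt(2) * y
  expect_equal(bic_score(y2, design, c(1, 2, 3)) -
                 bic_score(y, design, c(1, 2, 3)), 100 * log(2))
  expect_warning(b <- bic_score(y, cbind(y), 1), "saturated")
  expect_equal(b, -Inf)
})

test_that("lambda tuning is order-invariant and returns the null fit on a one-point grid", {
  set.seed(203)
  z <- matrix(rnorm(300), 50, 6)
  beta <- c(1.5, -1.5, 1, -1, 0, 0)
  y <- as.numeric(z %*% beta) + rnorm(50)
  lmax <- lambda_max(y, z)
  one <- tune_lambda(y, z, grid = lmax)
  expect_equal(one$lambda_opt, lmax)
  expect_equal(unname(one$fit$beta), rep(0, 6))
  grid <- lmax * c(0.05, 0.5, 0.01, 1, 0.2)
  t1 <- tune_lambda(y, z, grid = grid)
  t2 <- tune_lambda(y, z, grid = rev(grid))
  expect_equal(t1$lambda_opt, t2$lambda_opt)
  expect_equal(t1$bic_table$bic, t2$bic_table$bic)
  expect_equal(nrow(t1$bic_table), 5)
})

test_that("BIC tuning recovers a strong support through the pipeline fit", {
  set.seed(204)
  z <- matrix(rnorm(1200), 200, 6)
  beta <- c(2, -2, 1.5, -1.5, 0, 0)
  y <- as.numeric(z %*% beta) + rnorm(200)
  tuned <- tune_lambda(y, z)
  expect_true(all(1:4 %in% which(tuned$fit$beta != 0)))
  expect_lt(tuned$lambda_opt, lambda_max(y, z))
})

test_that("the full pipeline is deterministic and recovers strong signals", {
  params <- synthetic_dm_parameters(60, seed = 20260101)
  tree <- simulation_tree(60)
  sim <- simulate_dataset(params, n = 200, setting = "I", seed = 301)
  s1 <- run_tcvs(sim$counts, tree = tree, y = sim$y, seed = 301)
  s2 <- run_tcvs(sim$counts, tree = tree, y = sim$y, seed = 301)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$threshold, s2$threshold)
  truth <- which(sim$beta != 0)
  expect_gte(length(intersect(s1$selected, truth)), 9)
  rates <- tpr_fpr(s1$selected, sim$beta)
  expect_lte(rates$fpr, 0.15)
  # ablations run on the same data
  s_classo <- run_tcvs(sim$counts, y = sim$y, variant = "classo")
  expect_gte(length(intersect(s_classo$selected, truth)), 9)
  expect_true(all(is.na(s_classo$result$w)))
  s_tlasso <- run_tcvs(sim$counts, tree = tree, y = sim$y,
                       variant = "tlasso")
  expect_setequal(s_tlasso$selected, which(s_tlasso$fit$beta != 0))
  expect_error(run_tcvs(sim$counts, y = sim$y, variant = "tlasso"), "tree")
})

test_that("selection results tidy, glance and serialize coherently", {
  params <- synthetic_dm_parameters(20, seed = 5)
  tree <- simulation_tree(20)
  sim <- simulate_dataset(params, n = 80,
                          beta = c(2, -2, rep(0, 18)), seed = 302)
  sel <- run_tcvs(sim$counts, tree = tree, y = sim$y, seed = 302)
  td <- tidy(sel)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 20)
  expect_equal(sum(td$selected), length(sel$selected))
  gl <- glance(sel)
  expect_equal(gl$n_selected, length(sel$selected))
  expect_s3_class(autoplot(sel), "ggplot")
  out <- tempfile()
  write_selection(sel, out)
  expect_true(file.exists(file.path(out, "selected.tsv")))
  expect_true(file.exists(file.path(out, "fit.json")))
  sel_tab <- read.delim(file.path(out, "selected.tsv"))
  expect_equal(nrow(sel_tab), 20)
})
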
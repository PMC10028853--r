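# Model-comparison tests: loss differences, conditional paired-t,
# bootstrap replicates, combined statistic, and per-gene orchestration.

const_model <- function(b0, ids = character(0)) {
  # intercept-only model via the package's own degenerate path
  m <- fit_enet(matrix(0, 10, 0), rep(b0, 10))
  m
}

test_that("squared_loss_diffs is the paired squared-error difference", {
  ma <- const_model(0)
  mb <- const_model(0)
  y <- rnorm(6)
  X <- matrix(0, 6, 0)
  expect_equal(squared_loss_diffs(ma, mb, X, y), rep(0, 6))

  # y = [1,2,3], predictions A exact, B constant zero
  mA <- const_model(2)   # predicts 2 everywhere
  mB <- const_model(0)
  d <- squared_loss_diffs(mA, mB, matrix(0, 3, 0), c(1, 2, 3))
  expect_equal(d, (c(1, 2, 3) - 2)^2 - c(1, 4, 9))
  # antisymmetry
  expect_equal(squared_loss_diffs(mB, mA, matrix(0, 3, 0), c(1, 2, 3)), -d)
})

test_that("conditional_t_test reproduces the closed-form examples", {
  r <- conditional_t_test(c(-1, 1))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r <- conditional_t_test(c(1, 2, 3))
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-10)   # 3.4641...
  expect_equal(r$df, 2)
  # closed-form t_2 tail: p = 2 * (1/2) (1 - t / sqrt(2 + t^2))
  expect_equal(r$p, 1 - r$t / sqrt(2 + r$t^2), tolerance = 1e-10)
  expect_equal(r$p, 0.0742, tolerance = 1e-3)

  # matches the textbook one-sample t-test on random inputs
  set.seed(7)
  for (rep in 1:10) {
    d <- rnorm(sample(5:40, 1), mean = runif(1, -0.3, 0.3))
    tt <- t.test(d)
    r <- conditional_t_test(d)
    expect_equal(r$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  }

  # degenerate: zero variance
  expect_equal(conditional_t_test(rep(0, 5))$p, 1)
  expect_equal(conditional_t_test(rep(2, 5))$p, 0)
  expect_true(conditional_t_test(rep(2, 5))$degenerate)
})

test_that("drab_statistic follows the printed arithmetic (divisor K)", {
  r <- drab_statistic(0, 0.01, c(0.1, 0.2), 10)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  r <- drab_statistic(0.5, 0.01, c(0.4, 0.5, 0.6), 20)
  expect_equal(r$var_boot, 0.02 / 3, tolerance = 1e-10)
  expect_equal(r$t, 0.5 / sqrt(0.01 + 0.02 / 3), tolerance = 1e-10)
  expect_equal(r$t, 3.873, tolerance = 1e-3)
  expect_equal(r$df, 19)

  # all replicates equal: reduces exactly to the conditional statistic
  d <- c(0.3, -0.1, 0.5, 0.2, 0, 0.4)
  cond <- conditional_t_test(d)
  r <- drab_statistic(mean(d), cond$var_test, rep(1.23, 5), length(d))
  expect_equal(r$t, cond$t, tolerance = 1e-12)
  expect_equal(r$p, cond$p, tolerance = 1e-12)

  # both variances zero
  expect_equal(drab_statistic(0, 0, c(1, 1), 5)$p, 1)
  expect_equal(drab_statistic(0.2, 0, c(1, 1), 5)$p, 0)
  expect_true(drab_statistic(0.2, 0, c(1, 1), 5)$degenerate)
})

test_that("bootstrap_reps: degenerate trainer, determinism, per-sample attribute", {
  prob <- make_problem(n = 30, p = 5, seed = 2)
  tr_const <- list(X = prob$X, y = rep(0, 30))   # constant response -> fixed model
  X_t <- prob$X[1:10, ]
  y_t <- prob$y[1:10]
  reps <- bootstrap_reps(tr_const, tr_const, X_t, y_t, K = 4, seed = 1)
  expect_equal(var(as.numeric(reps)), 0)

  tr_a <- list(X = prob$X, y = prob$y)
  tr_b <- list(X = prob$X, y = rev(prob$y))
  r1 <- bootstrap_reps(tr_a, tr_b, X_t, y_t, K = 5, seed = 42)
  r2 <- bootstrap_reps(tr_a, tr_b, X_t, y_t, K = 5, seed = 42)
  expect_identical(r1, r2)
  ps <- attr(r1, "per_sample")
  expect_equal(dim(ps), c(5L, 10L))
  expect_equal(rowMeans(ps), as.numeric(r1))
  expect_error(bootstrap_reps(tr_a, tr_b, X_t, y_t, K = 1), "at least 2")
})

test_that("a shared resampling plan makes context swap an exact mirror", {
  prob_a <- make_problem(n = 40, p = 6, seed = 5)
  prob_b <- make_problem(n = 40, p = 6, seed = 6)
  X_t <- make_problem(n = 15, p = 6, seed = 7)$X
  y_t <- rnorm(15)
  plan <- lapply(1:4, function(k) list(idx_a = sample(40, 40, TRUE),
                                       idx_b = sample(40, 40, TRUE),
                                       seed_a = 100 + k, seed_b = 200 + k))
  swapped <- lapply(plan, function(pl) list(idx_a = pl$idx_b, idx_b = pl$idx_a,
                                            seed_a = pl$seed_b,
                                            seed_b = pl$seed_a))
  ra <- bootstrap_reps(list(X = prob_a$X, y = prob_a$y),
                       list(X = prob_b$X, y = prob_b$y), X_t, y_t,
                       K = 4, plan = plan, seed = 1)
  rb <- bootstrap_reps(list(X = prob_b$X, y = prob_b$y),
                       list(X = prob_a$X, y = prob_a$y), X_t, y_t,
                       K = 4, plan = swapped, seed = 1)
  expect_equal(as.numeric(ra), -as.numeric(rb), tolerance = 1e-12)
})

test_that("bootstrap variance tracks the true training-set variance of the mean loss diff", {
  # ground truth: redraw independent training sets many times and measure
  # the spread of the mean loss difference; the bootstrap estimate from one
  # training set should agree to well within a factor of 3
  n_tr <- 80
  n_te <- 60
  p <- 15
  seed0 <- 123
  gen <- function(seed) {
    G <- sim_genotypes(n_tr, p, maf = 0.3, seed = seed)
    beta <- numeric(p)
    beta[1:3] <- 0.4
    y <- sim_expression(G, beta, noise_var = 1, seed = seed + 1)
    list(X = scale(G$dosages), y = drop(scale(y)))
  }
  test_data <- gen(seed0)
  X_t <- test_data$X[1:n_te, ]
  y_t <- test_data$y[1:n_te]

  mc <- vapply(1:200, function(r) {
    da <- gen(1000 + r)
    db <- gen(5000 + r)
    ma <- fit_enet(da$X, da$y, seed = r, thresh = 1e-5)
    mb <- fit_enet(db$X, db$y, seed = -r, thresh = 1e-5)
    mean(squared_loss_diffs(ma, mb, X_t, y_t))
  }, numeric(1))
  truth <- var(mc)

  da <- gen(31)
  db <- gen(32)
  reps <- bootstrap_reps(da, db, X_t, y_t, K = 50, seed = 9, thresh = 1e-5)
  est <- mean((reps - mean(reps))^2)
  expect_gt(est, truth / 3)
  expect_lt(est, truth * 3)
})

test_that("test_gene returns a complete result and flags untestable genes", {
  prob <- make_problem(n = 90, p = 8, seed = 11)
  adj <- make_adjusted(prob$X[1:30, ], prob$y[1:30],
                       prob$X[31:60, ], prob$y[31:60],
                       prob$X[61:90, ], prob$y[61:90])
  res <- test_gene(adj, gene_id = "g1", K = 6, seed = 3)
  expect_s3_class(res, "drab_result")
  expect_equal(res$status, "ok")
  expect_equal(res$df, 29)
  expect_gte(res$p_drab, res$p_cond)   # denominator dominance
  expect_true(res$p_drab >= 0 && res$p_drab <= 1)

  # determinism and independence from other computations
  res2 <- test_gene(adj, gene_id = "g1", K = 6, seed = 3)
  expect_identical(res, res2)

  # untestable: no cis-SNPs
  adj0 <- make_adjusted(matrix(0, 30, 0), prob$y[1:30],
                        matrix(0, 30, 0), prob$y[31:60],
                        matrix(0, 30, 0), prob$y[61:90],
                        untestable = "no cis-SNPs")
  res0 <- test_gene(adj0, gene_id = "g0", K = 4, seed = 1)
  expect_equal(res0$status, "untestable")
  expect_true(is.na(res0$p_drab))
})
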
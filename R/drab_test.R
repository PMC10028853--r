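# Stage 2: model-comparison tests.
#
# Two tests are provided for each gene. The conditional paired-t test
# compares the two specific fitted models: its statistic divides the mean
# per-sample squared-error difference by the test-set sampling variance
# alone, so it answers "are these two fitted prediction rules equally
# accurate?". The bootstrap test adds a second variance component that
# captures how much the mean loss difference moves when both models are
# retrained on resampled training sets (feature selection, coefficient
# estimation, and penalty tuning are all rerun per replicate). Its
# denominator is
#   var_test + (1/K) * sum_k (dbar*_k - mean(dbar*))^2
# (bootstrap variance with divisor K), and the statistic is referred to a
# Student t distribution with |D_T| - 1 degrees of freedom. Because the
# added term is non-negative, the bootstrap p-value can never undercut the
# conditional one.

#' Per-sample squared-error loss differences
#'
#' For each test individual i, `(y_i - yhat_A_i)^2 - (y_i - yhat_B_i)^2`.
#'
#' @param model_a,model_b Fitted models with a `predict` method (e.g.
#'   [fit_enet()] output).
#' @param X_t Test-set genotype matrix.
#' @param y_t Test-set expression vector.
#' @return Numeric vector of per-sample loss differences.
#' @export
squared_loss_diffs <- function(model_a, model_b, X_t, y_t) {
  pa <- stats::predict(model_a, X_t)
  pb <- stats::predict(model_b, X_t)
  y_t <- as.numeric(y_t)
  if (length(pa) != length(y_t) || length(pb) != length(y_t))
    stopf("prediction length (%d, %d) does not match test-set size %d",
          length(pa), length(pb), length(y_t))
  (y_t - pa)^2 - (y_t - pb)^2
}

#' Conditional paired-t model comparison
#'
#' Paired t-test on the per-sample loss differences: statistic
#' `mean(diffs) / sqrt(var_test)` with
#' `var_test = sum((diffs - mean)^2) / (n (n - 1))`, referred to Student's t
#' with n - 1 degrees of freedom (two-sided). Valid only conditionally on
#' the specific pair of fitted models.
#'
#' @param diffs Loss-difference vector (length >= 2).
#' @return List with `t`, `df`, `p`, `var_test`, `degenerate`.
#' @export
conditional_t_test <- function(diffs) {
  n <- length(diffs)
  if (n < 2) stopf("need at least 2 paired differences")
  m <- mean(diffs)
  v <- sum((diffs - m)^2) / (n * (n - 1))
  if (v == 0) {
    return(list(t = if (m == 0) 0 else sign(m) * Inf, df = n - 1,
                p = if (m == 0) 1 else 0, var_test = 0, degenerate = TRUE))
  }
  t <- m / sqrt(v)
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1),
       var_test = v, degenerate = FALSE)
}

#' Bootstrap replicates of the mean loss difference
#'
#' For each of K replicates, rows of the two training sets are resampled
#' independently with replacement at their original sizes, both models are
#' retrained from scratch (including the cross-validated penalty selection),
#' and the mean loss difference is re-evaluated on the fixed test set. A
#' replicate whose resampled response is constant yields an intercept-only
#' model rather than being skipped, preserving K.
#'
#' @param train_a,train_b Lists with elements `X`, `y` for the two training
#'   sets.
#' @param X_t,y_t Fixed test set.
#' @param K Number of bootstrap replicates (default 50).
#' @param seed Master seed; each replicate uses an independent derived
#'   substream, so results do not depend on evaluation order.
#' @param alpha,n_folds,lambda_grid_size,thresh Passed to [fit_enet()].
#' @param plan Optional precomputed resampling plan: a list of K lists with
#'   `idx_a`, `idx_b` row indices and optionally `seed_a`, `seed_b` CV fold
#'   seeds. Overrides the seed-driven resampling (used e.g. to share one
#'   plan between a run and its context-swapped mirror).
#' @return Numeric vector of K mean loss differences. The per-sample
#'   loss-difference matrix (K x n_test) is attached as attribute
#'   `"per_sample"`.
#' @export
bootstrap_reps <- function(train_a, train_b, X_t, y_t, K = 50, seed = 1,
                           alpha = 0.5, n_folds = 5, lambda_grid_size = 100,
                           thresh = 1e-7, plan = NULL) {
  if (K < 2) stopf("need at least 2 bootstrap replicates")
  n_a <- length(train_a$y)
  n_b <- length(train_b$y)
  n_t <- length(y_t)
  reps <- numeric(K)
  per_sample <- matrix(NA_real_, K, n_t)
  for (k in seq_len(K)) {
    if (is.null(plan)) {
      ia <- with_seed(derive_seed(seed, "boot-resample-a", k),
                      sample.int(n_a, n_a, replace = TRUE))
      ib <- with_seed(derive_seed(seed, "boot-resample-b", k),
                      sample.int(n_b, n_b, replace = TRUE))
      seed_a <- derive_seed(seed, "boot-cv-a", k)
      seed_b <- derive_seed(seed, "boot-cv-b", k)
    } else {
      ia <- plan[[k]]$idx_a
      ib <- plan[[k]]$idx_b
      seed_a <- plan[[k]]$seed_a %||% derive_seed(seed, "boot-cv-a", k)
      seed_b <- plan[[k]]$seed_b %||% derive_seed(seed, "boot-cv-b", k)
    }
    ma <- fit_enet(train_a$X[ia, , drop = FALSE], train_a$y[ia], alpha = alpha,
                   n_folds = n_folds, seed = seed_a,
                   lambda_grid_size = lambda_grid_size, thresh = thresh)
    mb <- fit_enet(train_b$X[ib, , drop = FALSE], train_b$y[ib], alpha = alpha,
                   n_folds = n_folds, seed = seed_b,
                   lambda_grid_size = lambda_grid_size, thresh = thresh)
    d <- squared_loss_diffs(ma, mb, X_t, y_t)
    per_sample[k, ] <- d
    reps[k] <- mean(d)
  }
  attr(reps, "per_sample") <- per_sample
  reps
}

#' Bootstrap model-comparison statistic
#'
#' `t = delta_bar / sqrt(var_test + var_boot)` where `var_boot` is the
#' bootstrap variance of the replicate means with divisor K, referred
#' two-sided to Student's t with `n_test - 1` degrees of freedom. When all
#' replicates coincide (`var_boot = 0`) the statistic reduces exactly to the
#' conditional paired-t statistic.
#'
#' @param delta_bar Mean loss difference of the full-sample models.
#' @param var_test Test-set sampling variance of `delta_bar` (see
#'   [conditional_t_test()]).
#' @param boot_reps Vector of bootstrap replicate means.
#' @param n_test Test-set size.
#' @return List with `t`, `df`, `p`, `var_boot`, `degenerate`.
#' @export
drab_statistic <- function(delta_bar, var_test, boot_reps, n_test) {
  if (n_test < 2) stopf("need a test set of at least 2 samples")
  if (length(boot_reps) < 2) stopf("need at least 2 bootstrap replicates")
  var_boot <- mean((boot_reps - mean(boot_reps))^2)
  den <- var_test + var_boot
  df <- n_test - 1
  if (den <= 0) {
    return(list(t = if (delta_bar == 0) 0 else sign(delta_bar) * Inf, df = df,
                p = if (delta_bar == 0) 1 else 0, var_boot = var_boot,
                degenerate = TRUE))
  }
  t <- delta_bar / sqrt(den)
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), var_boot = var_boot,
       degenerate = FALSE)
}

#' Test one gene for differential cis-genetic regulation
#'
#' Trains the two context-specific elastic-net models on their full training
#' splits, computes both the conditional paired-t p-value and the bootstrap
#' test p-value on the test split, and records sparsity diagnostics.
#'
#' @param adjusted An `adjusted_gene_data` object from
#'   [prepare_gene_data()].
#' @param gene_id Gene identifier carried into the result.
#' @param K Number of bootstrap replicates (default 50).
#' @param seed Master seed; all randomness (CV folds, resampling) is derived
#'   from `(seed, gene_id)`, so per-gene results are invariant to gene-list
#'   order.
#' @param alpha,n_folds,lambda_grid_size,thresh Passed to [fit_enet()].
#' @param keep_boot Keep the bootstrap replicate vector (with its per-sample
#'   matrix) in the result.
#' @return A `drab_result` list: `gene_id`, `n_train`, `n_test`,
#'   `delta_bar`, `t_drab`, `df`, `p_drab`, `t_cond`, `p_cond`,
#'   `var_test`, `var_boot`, `n_selected_a`, `n_selected_b`, `status`
#'   (`"ok"`, `"untestable"`, or `"degenerate"`).
#' @export
test_gene <- function(adjusted, gene_id = "gene", K = 50, seed = 1,
                      alpha = 0.5, n_folds = 5, lambda_grid_size = 100,
                      thresh = 1e-7, keep_boot = FALSE) {
  stopifnot(inherits(adjusted, "adjusted_gene_data"))
  base <- list(gene_id = gene_id,
               n_train = length(adjusted$a$y %||% numeric(0)),
               n_test = length(adjusted$t$y %||% numeric(0)),
               delta_bar = NA_real_, t_drab = NA_real_, df = NA_integer_,
               p_drab = NA_real_, t_cond = NA_real_, p_cond = NA_real_,
               var_test = NA_real_, var_boot = NA_real_,
               n_selected_a = NA_integer_, n_selected_b = NA_integer_,
               status = "ok")
  if (is.character(adjusted$untestable)) {
    base$status <- "untestable"
    base$reason <- adjusted$untestable
    return(structure(base, class = "drab_result"))
  }

  ma <- fit_enet(adjusted$a$X, adjusted$a$y, alpha = alpha, n_folds = n_folds,
                 seed = derive_seed(seed, gene_id, "fit-a"),
                 lambda_grid_size = lambda_grid_size, thresh = thresh)
  mb <- fit_enet(adjusted$b$X, adjusted$b$y, alpha = alpha, n_folds = n_folds,
                 seed = derive_seed(seed, gene_id, "fit-b"),
                 lambda_grid_size = lambda_grid_size, thresh = thresh)
  diffs <- squared_loss_diffs(ma, mb, adjusted$t$X, adjusted$t$y)
  cond <- conditional_t_test(diffs)
  reps <- bootstrap_reps(adjusted$a, adjusted$b, adjusted$t$X, adjusted$t$y,
                         K = K, seed = derive_seed(seed, gene_id, "boot"),
                         alpha = alpha, n_folds = n_folds,
                         lambda_grid_size = lambda_grid_size, thresh = thresh)
  db <- mean(diffs)
  drab <- drab_statistic(db, cond$var_test, reps, length(diffs))

  base$delta_bar <- db
  base$t_drab <- drab$t
  base$df <- drab$df
  base$p_drab <- drab$p
  base$t_cond <- cond$t
  base$p_cond <- cond$p
  base$var_test <- cond$var_test
  base$var_boot <- drab$var_boot
  base$n_selected_a <- ma$n_selected
  base$n_selected_b <- mb$n_selected
  if (cond$degenerate || drab$degenerate) base$status <- "degenerate"
  if (keep_boot) base$boot_reps <- reps
  structure(base, class = "drab_result")
}

#' @export
print.drab_result <- function(x, ...) {
  cat(sprintf("drab_result %s [%s]: delta_bar = %s, p_drab = %s, p_cond = %s\n",
              x$gene_id, x$status, format(x$delta_bar, digits = 4),
              format(x$p_drab, digits = 4), format(x$p_cond, digits = 4)))
  invisible(x)
}

#' @export
as.data.frame.drab_result <- function(x, ...) {
  data.frame(gene_id = x$gene_id, n_train = x$n_train, n_test = x$n_test,
             delta_loss = x$delta_bar, t_drab = x$t_drab,
             df = if (is.na(x$df)) NA_integer_ else as.integer(x$df),
             p_drab = x$p_drab, p_conditional = x$p_cond,
             n_snps_selected_A = x$n_selected_a,
             n_snps_selected_B = x$n_selected_b,
             status = x$status, stringsAsFactors = FALSE)
}
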
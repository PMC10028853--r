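# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the elastic-net oracle is a proximal-gradient
# solver, the HWE oracle enumerates tables with a direct combinatorial
# formula, and the residualization oracle uses the normal equations.

# Proximal-gradient (ISTA) solver for
#   (1/2N) ||y - b0 - X b||^2 + lambda ((1-alpha)/2 ||b||^2 + alpha ||b||_1)
# run to tight tolerance. Independent of glmnet's coordinate descent.
prox_enet_oracle <- function(X, y, lambda, alpha, tol = 1e-12, max_iter = 2e5) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  L <- max(eigen(crossprod(X) / n, symmetric = TRUE, only.values = TRUE)$values) +
    lambda * (1 - alpha)
  step <- 1 / L
  beta <- numeric(p)
  b0 <- mean(y)
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (it in seq_len(max_iter)) {
    r <- y - b0 - drop(X %*% beta)
    grad <- -crossprod(X, r) / n + lambda * (1 - alpha) * beta
    beta_new <- soft(beta - step * grad, step * lambda * alpha)
    b0_new <- mean(y - drop(X %*% beta_new))
    delta <- max(abs(beta_new - beta), abs(b0_new - b0))
    beta <- drop(beta_new)
    b0 <- b0_new
    if (delta < tol) break
  }
  list(intercept = b0, beta = beta)
}

# Direct-enumeration HWE mid-p oracle: probability of each heterozygote
# count from the closed-form conditional distribution
#   P(h | n, n_rare) = n! / (n1! h! n2!) * 2^h * n_rare! n_common! / (2n)!
# computed in log space, no recurrence.
hwe_midp_oracle <- function(n_hom_a1, n_het, n_hom_a2) {
  n <- n_hom_a1 + n_het + n_hom_a2
  n_rare <- min(2 * n_hom_a1 + n_het, 2 * n_hom_a2 + n_het)
  n_common <- 2 * n - n_rare
  h_all <- seq(n_rare %% 2, min(n_rare, n_common), by = 2)
  logp <- vapply(h_all, function(h) {
    n1 <- (n_rare - h) / 2
    n2 <- (n_common - h) / 2
    lfactorial(n) - lfactorial(n1) - lfactorial(h) - lfactorial(n2) +
      h * log(2) + lfactorial(n_rare) + lfactorial(n_common) - lfactorial(2 * n)
  }, numeric(1))
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, h_all)]
  sum(probs[probs <= p_obs * (1 + 1e-10)]) - 0.5 * p_obs
}

# Normal-equations least-squares residuals.
residualize_oracle <- function(values, C) {
  X <- cbind(1, C)
  B <- solve(crossprod(X), crossprod(X, as.matrix(values)))
  out <- as.matrix(values) - X %*% B
  if (is.null(dim(values))) drop(out) else out
}

# Small standardized regression problem with sparse signal, for elastic-net
# and test-statistic fixtures.
make_problem <- function(n, p, n_causal = 3, h2 = 0.4, seed = 1, maf = 0.3) {
  withr_seed <- function(code) drabr:::with_seed(seed, code)
  withr_seed({
    X <- matrix(rbinom(n * p, 2, maf), n, p)
    keep <- apply(X, 2, var) > 0
    X <- scale(X[, keep, drop = FALSE])
    colnames(X) <- paste0("v", seq_len(ncol(X)))
    beta <- numeric(ncol(X))
    beta[sample(ncol(X), min(n_causal, ncol(X)))] <- rnorm(min(n_causal, ncol(X)))
    gpart <- drop(X %*% beta)
    if (var(gpart) > 0) gpart <- gpart * sqrt(h2 / var(gpart))
    y <- drop(scale(gpart + rnorm(n, sd = sqrt(1 - h2))))
    list(X = X, y = y)
  })
}

# Adjusted-gene-data object built directly from matrices, bypassing the
# preprocessing pipeline (for unit tests of test_gene).
make_adjusted <- function(Xa, ya, Xb, yb, Xt, yt, untestable = FALSE) {
  structure(list(a = list(X = Xa, y = ya), b = list(X = Xb, y = yb),
                 t = list(X = Xt, y = yt),
                 variant_ids = colnames(Xa), untestable = untestable),
            class = "adjusted_gene_data")
}
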
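# Stage 0: splits, cis windows, residualization, pruning/standardization.

test_that("make_splits honors mode contracts and is deterministic", {
  ids <- paste0("s", 1:9)
  sp <- make_splits(ids, mode = "thirds", seed = 3)
  expect_equal(lengths(sp[c("idx_a", "idx_b", "idx_t")]),
               c(idx_a = 3L, idx_b = 3L, idx_t = 3L))
  expect_length(intersect(sp$idx_t, union(sp$idx_a, sp$idx_b)), 0)
  expect_length(intersect(sp$idx_a, sp$idx_b), 0)

  ids2 <- paste0("s", 1:60)
  full <- make_splits(ids2, mode = "auto", seed = 5, overlap_fraction = 1)
  expect_setequal(full$idx_a, full$idx_b)
  expect_length(intersect(full$idx_t, full$idx_a), 0)

  expect_equal(make_splits(ids2, seed = 7), make_splits(ids2, seed = 7))
  expect_false(identical(make_splits(ids2, seed = 7), make_splits(ids2, seed = 8)))

  expect_error(make_splits(paste0("s", 1:8)), "at least 9")
  # custom splits violating the invariants are rejected
  expect_error(make_splits(ids2, mode = "custom",
                           custom = list(idx_a = 1:10, idx_b = 11:20, idx_t = 15:30)),
               "disjoint")
  expect_error(make_splits(ids2, mode = "custom",
                           custom = list(idx_a = 1:10, idx_b = 11:19, idx_t = 30:40)),
               "equal cardinality")
})

test_that("split invariants hold across random configurations", {
  set.seed(44)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    ov <- sample(c(0, 0.25, 0.5, 1), 1)
    tf <- runif(1, 0.1, 0.4)
    sp <- make_splits(paste0("s", seq_len(n)), mode = "auto", seed = rep,
                      overlap_fraction = ov, min_test_fraction = tf)
    expect_equal(length(sp$idx_a), length(sp$idx_b))
    expect_length(intersect(sp$idx_t, union(sp$idx_a, sp$idx_b)), 0)
    expect_gte(length(sp$idx_t), ceiling(n * tf))
    shared <- length(intersect(sp$idx_a, sp$idx_b))
    expect_equal(shared, round(ov * length(sp$idx_a)))
  }
})

test_that("cis_window applies the symmetric window with clipping", {
  g <- list(chrom = "2", tss = 600000, tes = 610000)
  expect_equal(cis_window(g, 500000),
               list(chrom = "2", start = 100000, end = 1110000))
  expect_equal(cis_window(list(chrom = "1", tss = 100, tes = 200), 500000),
               list(chrom = "1", start = 1, end = 500200))
  expect_equal(cis_window(g, 0), list(chrom = "2", start = 600000, end = 610000))
  expect_error(cis_window(list(chrom = "1", tss = 5, tes = 1)), "tss > tes")
})

test_that("extract_cis uses closed intervals per chromosome and matches a scan", {
  G <- sim_genotypes(n = 5, p = 6, maf = 0.4, seed = 2,
                     pos = c(100, 200, 300, 400, 500, 600))
  G$variants$chrom <- c("1", "1", "2", "1", "1", "1")
  win <- list(chrom = "1", start = 200, end = 500)
  got <- extract_cis(G, win)
  # boundary variants (200, 500) included; chr2 variant at 300 excluded
  expect_equal(got$variants$pos, c(200, 400, 500))

  set.seed(77)
  Gr <- sim_genotypes(n = 4, p = 50, maf = 0.3, seed = 8,
                      pos = sample.int(1e6, 50))
  Gr$variants$chrom <- sample(c("1", "2"), 50, replace = TRUE)
  win <- list(chrom = "2", start = 2e5, end = 8e5)
  scan <- which(vapply(seq_len(50), function(j) {
    Gr$variants$chrom[j] == "2" && Gr$variants$pos[j] >= 2e5 &&
      Gr$variants$pos[j] <= 8e5
  }, logical(1)))
  expect_equal(extract_cis(Gr, win)$variants$id, Gr$variants$id[scan])
})

test_that("residualize matches the normal equations and is a projection", {
  set.seed(12)
  C <- matrix(rnorm(60), 20, 3)
  V <- matrix(rnorm(40), 20, 2)

  expect_equal(residualize(V, C), residualize_oracle(V, C), tolerance = 1e-10,
               ignore_attr = TRUE)
  # intercept-only: centering
  expect_equal(residualize(V), sweep(V, 2, colMeans(V)), ignore_attr = TRUE)
  # perfect fit: a covariate column residualizes to zero
  expect_lt(max(abs(residualize(C[, 1], C))), 1e-10)
  # projection idempotence
  expect_equal(residualize(residualize(V, C), C), residualize(V, C),
               tolerance = 1e-10, ignore_attr = TRUE)
  # residuals orthogonal to every covariate column
  R <- residualize(V, C)
  expect_lt(max(abs(crossprod(C, R))) / nrow(C), 1e-8)
  # rank-deficient covariates are dropped with a warning, then proceed
  expect_warning(R2 <- residualize(V, cbind(C, C[, 1])), "dependent")
  expect_equal(R2, R, tolerance = 1e-10, ignore_attr = TRUE)
})

prune_fixture <- function(seed = 21, n = 30, p = 8) {
  set.seed(seed)
  mk <- function() {
    raw <- matrix(rbinom(n * p, 2, 0.4), n, p)
    list(geno_raw = raw, geno_resid = residualize(raw),
         expr_resid = residualize(rnorm(n)))
  }
  out <- list(a = mk(), b = mk(), t = mk(), variant_ids = paste0("v", 1:p))
  out
}

test_that("standardize_and_prune drops split-monomorphic columns everywhere", {
  sd <- prune_fixture()
  sd$t$geno_raw[, 4] <- 1               # constant in D_T only
  sd$t$geno_resid <- residualize(sd$t$geno_raw)
  adj <- standardize_and_prune(sd)
  expect_false("v4" %in% adj$variant_ids)
  for (s in c("a", "b", "t")) expect_false("v4" %in% colnames(adj[[s]]$X))

  # pruned set equals a brute-force per-split variance scan
  keep_scan <- vapply(1:8, function(j) {
    all(vapply(c("a", "b", "t"),
               function(s) var(sd[[s]]$geno_raw[, j]) > 0, logical(1)))
  }, logical(1))
  expect_equal(adj$variant_ids, paste0("v", 1:8)[keep_scan])
})

test_that("adjusted data is standardized within each split", {
  adj <- standardize_and_prune(prune_fixture(seed = 5))
  for (s in c("a", "b", "t")) {
    expect_lt(max(abs(colMeans(adj[[s]]$X))), 1e-10)
    expect_lt(max(abs(apply(adj[[s]]$X, 2, var) - 1)), 1e-8)
    expect_lt(abs(mean(adj[[s]]$y)), 1e-10)
    expect_lt(abs(var(adj[[s]]$y) - 1), 1e-8)
  }
})

test_that("constant expression in a split flags the gene untestable", {
  sd <- prune_fixture()
  sd$b$expr_resid <- rep(0, 30)
  adj <- standardize_and_prune(sd)
  expect_match(adj$untestable, "split B")
})

test_that("split adjustments are independent: perturbing one split leaves others unchanged", {
  sd1 <- prune_fixture(seed = 61)
  sd2 <- sd1
  set.seed(99)
  sd2$t$expr_resid <- residualize(rnorm(30))
  sd2$t$geno_resid <- sd2$t$geno_resid + 0  # same genotypes, new expression
  a1 <- standardize_and_prune(sd1)
  a2 <- standardize_and_prune(sd2)
  expect_equal(a1$a, a2$a)
  expect_equal(a1$b, a2$b)
  expect_false(isTRUE(all.equal(a1$t$y, a2$t$y)))
})

test_that("prepare_gene_data wires splits, covariates, and pruning together", {
  G <- sim_genotypes(n = 90, p = 12, maf = 0.4, seed = 3, pos = 1:12 * 100)
  covar <- matrix(rnorm(180), 90, 2, dimnames = list(NULL, c("c1", "c2")))
  y <- drop(G$dosages %*% c(rep(0.3, 3), rep(0, 9))) + covar %*% c(1, -1) + rnorm(90)
  sp <- make_splits(G$sample_ids, mode = "thirds", seed = 4)
  adj <- prepare_gene_data(G, y, y, y, covar, sp)
  expect_false(is.character(adj$untestable))
  expect_equal(nrow(adj$a$X), 30)
  expect_lt(max(abs(colMeans(adj$t$X))), 1e-10)
  # test-split residuals orthogonal to test-split covariates
  expect_lt(max(abs(crossprod(covar[sp$idx_t, ], adj$t$y))) / 30, 1e-8)
})
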
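# Stage 0: training/test split construction, cis-window extraction,
# covariate residualization, monomorphic pruning, and within-split
# standardization.

#' Construct and validate a split assignment
#'
#' A split assignment carries the two training index sets D_A and D_B and
#' the test index set D_T. The test set must be disjoint from both training
#' sets (unbiased model comparison) and the training sets must have equal
#' cardinality (so neither fitted model is systematically less stable).
#' D_A and D_B may overlap only when overlap was explicitly requested.
#'
#' @param idx_a,idx_b,idx_t Integer sample indices (into the cohort's sample
#'   id vector) for D_A, D_B, D_T.
#' @param n Cohort size the indices refer to.
#' @param allow_overlap Whether a non-empty D_A intersect D_B is permitted.
#' @return An object of class `split_assignment`.
#' @export
split_assignment <- function(idx_a, idx_b, idx_t, n, allow_overlap = FALSE) {
  idx_a <- as.integer(idx_a); idx_b <- as.integer(idx_b); idx_t <- as.integer(idx_t)
  for (ix in list(idx_a, idx_b, idx_t)) {
    if (anyDuplicated(ix)) stopf("split index sets must not contain duplicates")
    if (length(ix) && (min(ix) < 1 || max(ix) > n)) stopf("split indices out of range 1..%d", n)
  }
  if (length(idx_a) != length(idx_b))
    stopf("training sets must have equal cardinality (|D_A| = %d, |D_B| = %d)",
          length(idx_a), length(idx_b))
  if (length(intersect(idx_t, union(idx_a, idx_b))))
    stopf("test set must be disjoint from both training sets")
  if (!allow_overlap && length(intersect(idx_a, idx_b)))
    stopf("training sets overlap but overlap was not requested")
  structure(list(idx_a = idx_a, idx_b = idx_b, idx_t = idx_t, n = n),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf("split_assignment: |D_A| = %d, |D_B| = %d (overlap %d), |D_T| = %d of %d samples\n",
              length(x$idx_a), length(x$idx_b), length(intersect(x$idx_a, x$idx_b)),
              length(x$idx_t), x$n))
  invisible(x)
}

#' Build training/test splits from a sample list
#'
#' `auto` mode reserves a configurable test fraction and makes the two
#' training sets as large as possible from the remainder; `thirds` mode
#' partitions the cohort into three equal subsets (the single-tissue
#' negative-control design); `custom` mode validates user-provided sets.
#' `overlap_fraction` > 0 makes D_A and D_B share that fraction of their
#' samples (D_T stays disjoint from both).
#'
#' @param sample_ids Character vector of available samples (>= 9).
#' @param mode One of `"auto"`, `"thirds"`, `"custom"`.
#' @param seed Integer seed; the assignment is deterministic given the seed.
#' @param overlap_fraction Fraction of each training set shared between D_A
#'   and D_B (default 0 = disjoint). Ignored with a warning in `thirds` mode.
#' @param min_test_fraction Minimum fraction of samples reserved for D_T in
#'   `auto` mode (default 0.25).
#' @param custom For `mode = "custom"`: list with `idx_a`, `idx_b`, `idx_t`
#'   (indices or sample ids).
#' @return A [split_assignment()].
#' @export
make_splits <- function(sample_ids, mode = c("auto", "thirds", "custom"),
                        seed = 1, overlap_fraction = 0,
                        min_test_fraction = 0.25, custom = NULL) {
  mode <- match.arg(mode)
  n <- length(sample_ids)
  if (n < 9) stopf("need at least 9 samples to form splits, got %d", n)
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stopf("overlap_fraction must lie in [0, 1]")

  if (mode == "custom") {
    if (is.null(custom)) stopf("custom mode requires the `custom` argument")
    ix <- lapply(custom[c("idx_a", "idx_b", "idx_t")], function(v) {
      if (is.character(v)) match(v, sample_ids) else as.integer(v)
    })
    if (anyNA(unlist(ix))) stopf("custom split references unknown samples")
    return(split_assignment(ix$idx_a, ix$idx_b, ix$idx_t, n,
                            allow_overlap = length(intersect(ix$idx_a, ix$idx_b)) > 0))
  }

  perm <- with_seed(seed, sample.int(n))

  if (mode == "thirds") {
    if (overlap_fraction > 0)
      warnf("overlap_fraction is ignored in thirds mode")
    k <- n %/% 3
    return(split_assignment(perm[seq_len(k)], perm[k + seq_len(k)],
                            perm[2 * k + seq_len(k)], n))
  }

  n_t <- max(ceiling(n * min_test_fraction), 1L)
  pool <- n - n_t
  # largest m with 2m - round(overlap * m) <= pool
  m <- pool
  while (m > 0 && 2 * m - round(overlap_fraction * m) > pool) m <- m - 1L
  if (m < 1) stopf("not enough samples left for training after the test set")
  shared <- as.integer(round(overlap_fraction * m))
  uniq <- m - shared
  idx_t <- perm[seq_len(n_t)]
  rest <- perm[-seq_len(n_t)]
  sh <- rest[seq_len(shared)]
  ua <- rest[shared + seq_len(uniq)]
  ub <- rest[shared + uniq + seq_len(uniq)]
  leftover <- rest[-seq_len(shared + 2L * uniq)]
  split_assignment(c(sh, ua), c(sh, ub), c(idx_t, leftover), n,
                   allow_overlap = shared > 0)
}

#' Cis window around a gene
#'
#' The cis locus extends `window_bp` base pairs upstream of the transcription
#' start site to `window_bp` downstream of the transcription end site,
#' clipped at position 1; coordinates are 1-based and the interval is closed.
#'
#' @param gene A row (list or one-row data.frame) with `chrom`, `tss`, `tes`.
#' @param window_bp Window size in base pairs (default 500000).
#' @return List with `chrom`, `start`, `end`.
#' @export
cis_window <- function(gene, window_bp = 500000) {
  if (window_bp < 0) stopf("window_bp must be non-negative")
  tss <- as.numeric(gene$tss); tes <- as.numeric(gene$tes)
  if (tss > tes) stopf("gene has tss > tes after canonicalization")
  list(chrom = as.character(gene$chrom),
       start = max(1, tss - window_bp),
       end = tes + window_bp)
}

#' Extract cis-window variants from a genotype matrix
#'
#' Keeps the columns whose position lies in the closed interval on the
#' matching chromosome, preserving original column order. An empty result is
#' allowed; downstream code flags the gene untestable.
#'
#' @param G A [genotype_matrix()].
#' @param interval A list with `chrom`, `start`, `end` (see [cis_window()]).
#' @return A [genotype_matrix()] restricted to the cis variants.
#' @export
extract_cis <- function(G, interval) {
  sel <- G$variants$chrom == interval$chrom &
    G$variants$pos >= interval$start & G$variants$pos <= interval$end
  subset_variants(G, sel)
}

#' Residualize values on covariates
#'
#' Least-squares residuals of each column of `values` on an intercept plus
#' the covariate columns. Rank-deficient covariate sets are handled by
#' dropping linearly dependent columns with a warning. With no covariates
#' this reduces to column centering.
#'
#' @param values Numeric vector or matrix; rows are samples aligned with `C`.
#' @param C Covariate matrix (samples x covariates) or `NULL`.
#' @return Residuals with the same shape as `values`.
#' @export
residualize <- function(values, C = NULL) {
  v <- as.matrix(values)
  n <- nrow(v)
  if (is.null(C) || NCOL(C) == 0) {
    res <- sweep(v, 2, colMeans(v))
  } else {
    C <- as.matrix(C)
    if (nrow(C) != n) stopf("covariate rows (%d) do not match value rows (%d)", nrow(C), n)
    X <- cbind(`(Intercept)` = 1, C)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      warnf("dropping linearly dependent covariate column(s): %s",
            paste(dropped, collapse = ", "))
      X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
      qx <- qr(X)
    }
    res <- qr.resid(qx, v)
  }
  if (is.null(dim(values))) drop(res) else res
}

#' Prune monomorphic variants and standardize per split
#'
#' A variant whose raw dosages are constant within any of the three splits
#' is removed from all splits, so both models always see the same feature
#' set. Surviving genotype-residual columns and the expression residuals are
#' then centered and scaled to unit sample variance (denominator n - 1)
#' within each split, independently, so that no test-set statistic leaks
#' into training data or vice versa.
#'
#' @param split_data A list with elements `a`, `b`, `t`, each a list holding
#'   `geno_raw` (raw dosage submatrix), `geno_resid` (covariate-residualized
#'   genotypes), and `expr_resid` (covariate-residualized expression vector);
#'   plus `variant_ids`.
#' @return An `adjusted_gene_data` object: per split `X` (standardized
#'   genotype matrix) and `y` (standardized expression), `variant_ids`, and
#'   `untestable` (FALSE or a reason string).
#' @export
standardize_and_prune <- function(split_data) {
  vids <- as.character(split_data$variant_ids)
  p <- length(vids)
  keep <- rep(TRUE, p)
  for (s in c("a", "b", "t")) {
    raw <- split_data[[s]]$geno_raw
    if (p > 0) keep <- keep & (matrixStats_colVars(raw) > 0)
  }

  out <- list(variant_ids = vids[keep], untestable = FALSE)
  for (s in c("a", "b", "t")) {
    X <- split_data[[s]]$geno_resid
    colnames(X) <- vids
    X <- X[, keep, drop = FALSE]
    y <- split_data[[s]]$expr_resid
    sy <- stats::sd(y)
    if (!is.finite(sy) || sy == 0) {
      out$untestable <- sprintf("constant expression in split %s", toupper(s))
      sy <- 1
    }
    y <- (y - mean(y)) / sy
    if (ncol(X) > 0) {
      X <- scale(X)
      # a column can be polymorphic in raw dosage yet constant after
      # residualization; treat as monomorphic
      bad <- !is.finite(colSums(X))
      if (any(bad)) {
        keep2 <- !bad
        X <- X[, keep2, drop = FALSE]
        out$variant_ids <- intersect(out$variant_ids, colnames(X))
      }
      attr(X, "scaled:center") <- NULL
      attr(X, "scaled:scale") <- NULL
    }
    out[[s]] <- list(X = X, y = y)
  }
  # harmonize feature sets if residual pruning differed across splits
  common <- out$variant_ids
  for (s in c("a", "b", "t")) {
    out[[s]]$X <- out[[s]]$X[, common, drop = FALSE]
  }
  if (length(common) == 0 && !is.character(out$untestable) && p > 0) {
    # all variants pruned: gene has no usable cis variation
    out$untestable <- "no polymorphic cis-SNPs in all splits"
  }
  if (p == 0) out$untestable <- "no cis-SNPs"
  class(out) <- "adjusted_gene_data"
  out
}

# colVars without a matrixStats dependency
matrixStats_colVars <- function(m) {
  if (ncol(m) == 0) return(numeric(0))
  n <- nrow(m)
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

#' Assemble per-gene adjusted data for the three splits
#'
#' Runs the full per-gene Stage 0 on one gene: subsets the cis genotype
#' matrix to each split's samples, residualizes genotypes and expression on
#' the covariates separately within each split, prunes monomorphic variants
#' across splits, and standardizes within splits.
#'
#' @param G_cis [genotype_matrix()] restricted to the gene's cis window,
#'   rows covering the cohort the split indices refer to.
#' @param expr_a,expr_b,expr_t Expression vectors over the full cohort for
#'   context A, context B, and the test context.
#' @param covar Covariate matrix over the full cohort (or `NULL`).
#' @param splits A [split_assignment()].
#' @return An `adjusted_gene_data` object (see [standardize_and_prune()]).
#' @export
prepare_gene_data <- function(G_cis, expr_a, expr_b, expr_t, covar, splits) {
  stopifnot(inherits(G_cis, "genotype_matrix"), inherits(splits, "split_assignment"))
  idx <- list(a = splits$idx_a, b = splits$idx_b, t = splits$idx_t)
  expr <- list(a = expr_a, b = expr_b, t = expr_t)
  sd <- list(variant_ids = G_cis$variants$id)
  for (s in names(idx)) {
    i <- idx[[s]]
    raw <- G_cis$dosages[i, , drop = FALSE]
    Cs <- if (is.null(covar)) NULL else covar[i, , drop = FALSE]
    if (!is.null(Cs) && ncol(Cs) > 0) {
      # drop covariates constant within this split (zero variance after
      # intersection) with a warning
      cv <- matrixStats_colVars(as.matrix(Cs))
      if (any(cv == 0)) {
        warnf("dropping zero-variance covariate(s) in split %s: %s", toupper(s),
              paste(colnames(Cs)[cv == 0], collapse = ", "))
        Cs <- Cs[, cv > 0, drop = FALSE]
      }
    }
    sd[[s]] <- list(geno_raw = raw,
                    geno_resid = residualize(raw, Cs),
                    expr_resid = residualize(expr[[s]][i], Cs))
  }
  standardize_and_prune(sd)
}
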
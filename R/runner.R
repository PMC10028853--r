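# Per-gene orchestration: configuration, the full pipeline over a gene
# list, multiple-testing correction, and calibration diagnostics.

#' Build a run configuration
#'
#' @param bfile PLINK prefix for the genotype files.
#' @param expr_a,expr_b Expression TSV paths for contexts A and B (genes x
#'   samples). For a single-tissue negative control the same file may be
#'   given twice.
#' @param annot Gene annotation TSV path.
#' @param test_context Which context's measured expression forms the test
#'   response: `"A"` or `"B"`. Required, with no default: the choice affects
#'   power (a test context with more expression variation detects subtler
#'   regulatory differences), so it must be made explicitly.
#' @param covar Optional covariate TSV path.
#' @param genes Optional gene list path; default is all annotated genes
#'   present in both expression matrices.
#' @param out Optional output directory; when given, `results.tsv` and a
#'   run log are written there.
#' @param window_bp Cis-window size in bp (default 500000).
#' @param boot_k Bootstrap replicates per gene (default 50).
#' @param alpha_mix Elastic-net mixing weight (default 0.5).
#' @param n_folds CV folds (default 5).
#' @param seed Master seed (default 1).
#' @param split_mode `"auto"`, `"thirds"`, or `"custom"` (see
#'   [make_splits()]).
#' @param overlap_fraction Training-set overlap fraction (default 0).
#' @param min_test_fraction Minimum test fraction in auto mode
#'   (default 0.25).
#' @param custom_splits Custom split list for `split_mode = "custom"`.
#' @param maf_min,hwe_p_min Variant QC thresholds (defaults 0.01, 1e-6).
#' @param lambda_grid_size,solver_thresh Elastic-net grid size and solver
#'   tolerance (defaults 100, 1e-7).
#' @return A validated `drab_config` list.
#' @export
drab_config <- function(bfile, expr_a, expr_b, annot, test_context,
                        covar = NULL, genes = NULL, out = NULL,
                        window_bp = 500000, boot_k = 50, alpha_mix = 0.5,
                        n_folds = 5, seed = 1, split_mode = "auto",
                        overlap_fraction = 0, min_test_fraction = 0.25,
                        custom_splits = NULL, maf_min = 0.01,
                        hwe_p_min = 1e-6, lambda_grid_size = 100,
                        solver_thresh = 1e-7) {
  if (missing(test_context) || !test_context %in% c("A", "B"))
    stopf("test_context must be \"A\" or \"B\" (no default: the choice affects power)")
  for (pth in c(paste0(bfile, c(".bed", ".bim", ".fam")), expr_a, expr_b, annot,
                covar, genes))
    if (!is.null(pth) && !file.exists(pth)) stopf("input file not found: %s", pth)
  stopifnot(window_bp >= 0, boot_k >= 2, alpha_mix >= 0, alpha_mix <= 1,
            n_folds >= 2, overlap_fraction >= 0, overlap_fraction <= 1,
            maf_min >= 0, maf_min <= 1, hwe_p_min >= 0, hwe_p_min <= 1)
  structure(list(bfile = bfile, expr_a = expr_a, expr_b = expr_b,
                 annot = annot, covar = covar, genes = genes, out = out,
                 test_context = test_context, window_bp = window_bp,
                 boot_k = boot_k, alpha_mix = alpha_mix, n_folds = n_folds,
                 seed = as.integer(seed), split_mode = split_mode,
                 overlap_fraction = overlap_fraction,
                 min_test_fraction = min_test_fraction,
                 custom_splits = custom_splits, maf_min = maf_min,
                 hwe_p_min = hwe_p_min,
                 lambda_grid_size = lambda_grid_size,
                 solver_thresh = solver_thresh),
            class = "drab_config")
}

# Donor policy when the two contexts have different donor sets: the test
# set is drawn from donors measured in the test context, preferring donors
# absent from the other context (those cannot train the other model
# anyway); the remaining donors with context-A (resp. B) data supply D_A
# (resp. D_B), trimmed to equal size. With overlap_fraction = 0 the
# training sets are kept disjoint.
two_context_splits <- function(geno_ids, donors_a, donors_b, test_context,
                               min_test_fraction, overlap_fraction, seed) {
  donors_test <- if (test_context == "A") donors_a else donors_b
  donors_other <- if (test_context == "A") donors_b else donors_a
  n_t <- max(ceiling(length(donors_test) * min_test_fraction), 1L)
  only_test <- setdiff(donors_test, donors_other)
  both <- intersect(donors_test, donors_other)
  ord <- with_seed(derive_seed(seed, "two-context-test"), {
    c(sample(only_test), sample(both))
  })
  test_ids <- ord[seq_len(min(n_t, length(ord)))]
  avail_a <- setdiff(donors_a, test_ids)
  avail_b <- setdiff(donors_b, test_ids)
  m <- min(length(avail_a), length(avail_b))
  if (overlap_fraction == 0) {
    shared_pool <- intersect(avail_a, avail_b)
    # partition shared donors so D_A and D_B stay disjoint
    half <- with_seed(derive_seed(seed, "two-context-shared"),
                      sample(shared_pool, length(shared_pool) %/% 2))
    a_pool <- setdiff(avail_a, setdiff(shared_pool, half))
    b_pool <- setdiff(avail_b, half)
    m <- min(length(a_pool), length(b_pool))
    ids_a <- with_seed(derive_seed(seed, "two-context-a"), sample(a_pool, m))
    ids_b <- with_seed(derive_seed(seed, "two-context-b"), sample(b_pool, m))
  } else {
    ids_a <- with_seed(derive_seed(seed, "two-context-a"), sample(avail_a, m))
    ids_b <- with_seed(derive_seed(seed, "two-context-b"), sample(avail_b, m))
  }
  split_assignment(match(ids_a, geno_ids), match(ids_b, geno_ids),
                   match(test_ids, geno_ids), length(geno_ids),
                   allow_overlap = TRUE)
}

#' Run the full differential-regulation pipeline
#'
#' Reads and aligns all inputs, applies variant QC, forms the
#' training/test splits, and runs both model-comparison tests for every
#' listed gene. A gene that fails unexpectedly is logged and reported with
#' an error status; the run only aborts on configuration or I/O errors.
#'
#' @param config A [drab_config()].
#' @param quiet Suppress the per-gene progress lines.
#' @return The results data.frame (one row per gene), invisibly also
#'   written to `<out>/results.tsv` when `out` is configured. Attributes:
#'   `qc_log` (variant QC removals), `splits` (the split assignment).
#' @export
drab_run <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "drab_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  t_start <- Sys.time()

  G <- read_plink(config$bfile)
  ea <- read_expression(config$expr_a)
  eb <- read_expression(config$expr_b)
  covar <- if (!is.null(config$covar)) read_covariates(config$covar)
  annot <- read_annotation(config$annot)
  gene_ids <- if (!is.null(config$genes)) read_gene_list(config$genes) else
    intersect(annot$gene_id, intersect(ea$gene_ids, eb$gene_ids))

  donors_a <- intersect(G$sample_ids, ea$sample_ids)
  donors_b <- intersect(G$sample_ids, eb$sample_ids)
  donors_all <- union(donors_a, donors_b)
  dropped <- length(G$sample_ids) - length(donors_all)
  if (dropped > 0)
    say("dropping %d genotyped samples with no expression data", dropped)
  cohort <- G$sample_ids[G$sample_ids %in% donors_all]
  G <- subset_samples(G, cohort)

  G <- apply_variant_qc(G, maf_min = config$maf_min,
                        hwe_p_min = config$hwe_p_min)
  qc <- attr(G, "qc_log")
  say("variant QC: %d variants kept (%s)", nrow(G$variants),
      paste(sprintf("%s=%d", qc$filter, qc$removed), collapse = ", "))

  if (setequal(donors_a, donors_b)) {
    splits <- make_splits(cohort, mode = config$split_mode,
                          seed = derive_seed(config$seed, "splits"),
                          overlap_fraction = config$overlap_fraction,
                          min_test_fraction = config$min_test_fraction,
                          custom = config$custom_splits)
  } else {
    splits <- two_context_splits(cohort, donors_a, donors_b,
                                 config$test_context,
                                 config$min_test_fraction,
                                 config$overlap_fraction, config$seed)
  }
  say("splits: |D_A| = |D_B| = %d, |D_T| = %d", length(splits$idx_a),
      length(splits$idx_t))
  if (length(splits$idx_a) < 100)
    warnf("training sets have only %d samples; test statistics may be unstable below 100",
          length(splits$idx_a))

  # per-context expression aligned to the cohort (NA where unmeasured)
  expr_vec <- function(E, gene) {
    v <- rep(NA_real_, length(cohort))
    j <- match(cohort, E$sample_ids)
    if (gene %in% E$gene_ids) v[!is.na(j)] <- E$values[gene, j[!is.na(j)]]
    v
  }
  covar_m <- if (!is.null(covar)) {
    cm <- matrix(NA_real_, length(cohort), length(covar$covariate_names),
                 dimnames = list(cohort, covar$covariate_names))
    j <- match(cohort, covar$sample_ids)
    if (anyNA(j)) stopf("covariate table lacks %d cohort samples", sum(is.na(j)))
    cm[] <- covar$values[j, , drop = FALSE]
    cm
  }

  results <- vector("list", length(gene_ids))
  for (gi in seq_along(gene_ids)) {
    g <- gene_ids[gi]
    t0 <- Sys.time()
    row <- tryCatch({
      arow <- annot[annot$gene_id == g, , drop = FALSE]
      if (nrow(arow) == 0) {
        res <- list(gene_id = g, n_train = length(splits$idx_a),
                    n_test = length(splits$idx_t), status = "untestable",
                    reason = "missing annotation")
        class(res) <- "drab_result"
        untestable_row(res)
      } else if (!(g %in% ea$gene_ids) || !(g %in% eb$gene_ids)) {
        res <- list(gene_id = g, n_train = length(splits$idx_a),
                    n_test = length(splits$idx_t), status = "untestable",
                    reason = "missing expression")
        class(res) <- "drab_result"
        untestable_row(res)
      } else {
        Gc <- extract_cis(G, cis_window(arow[1, ], config$window_bp))
        ya <- expr_vec(ea, g)
        yb <- expr_vec(eb, g)
        yt <- if (config$test_context == "A") ya else yb
        adjusted <- prepare_gene_data(Gc, ya, yb, yt, covar_m, splits)
        res <- test_gene(adjusted, gene_id = g, K = config$boot_k,
                         seed = config$seed, alpha = config$alpha_mix,
                         n_folds = config$n_folds,
                         lambda_grid_size = config$lambda_grid_size,
                         thresh = config$solver_thresh)
        as.data.frame(res)
      }
    }, error = function(e) {
      say("gene %s failed: %s", g, conditionMessage(e))
      data.frame(gene_id = g, n_train = length(splits$idx_a),
                 n_test = length(splits$idx_t), delta_loss = NA_real_,
                 t_drab = NA_real_, df = NA_integer_, p_drab = NA_real_,
                 p_conditional = NA_real_, n_snps_selected_A = NA_integer_,
                 n_snps_selected_B = NA_integer_, status = "error",
                 stringsAsFactors = FALSE)
    })
    results[[gi]] <- row
    say("gene=%s status=%s p_drab=%s p_cond=%s n_sel_A=%s n_sel_B=%s elapsed=%.2fs",
        g, row$status, format(row$p_drab, digits = 3),
        format(row$p_conditional, digits = 3), row$n_snps_selected_A,
        row$n_snps_selected_B, as.numeric(Sys.time() - t0, units = "secs"))
  }
  tab <- do.call(rbind, results)
  attr(tab, "qc_log") <- qc
  attr(tab, "splits") <- splits

  if (!is.null(config$out)) {
    dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
    write_results(tab, file.path(config$out, "results.tsv"))
    n_ok <- sum(tab$status == "ok")
    writeLines(sprintf(
      "genes=%d tested=%d untestable=%d errors=%d elapsed=%.1fs seed=%d",
      nrow(tab), n_ok, sum(tab$status == "untestable"),
      sum(tab$status == "error"),
      as.numeric(Sys.time() - t_start, units = "secs"), config$seed),
      file.path(config$out, "run_log.txt"))
  }
  say("done: %d genes in %.1fs", nrow(tab),
      as.numeric(Sys.time() - t_start, units = "secs"))
  invisible(tab)
}

untestable_row <- function(res) {
  data.frame(gene_id = res$gene_id, n_train = res$n_train,
             n_test = res$n_test, delta_loss = NA_real_, t_drab = NA_real_,
             df = NA_integer_, p_drab = NA_real_, p_conditional = NA_real_,
             n_snps_selected_A = NA_integer_, n_snps_selected_B = NA_integer_,
             status = res$status, stringsAsFactors = FALSE)
}

#' Bonferroni multiple-testing correction
#'
#' Declares significance at `alpha / m`, where `m` counts the finite
#' p-values (genes with no p-value, e.g. untestable ones, do not count
#' toward the correction).
#'
#' @param p_values Numeric vector of p-values (NAs allowed).
#' @param alpha Family-wise error level (default 0.05).
#' @return List with `threshold`, `significant` (logical vector, `FALSE`
#'   where p is missing), and `m`.
#' @export
bonferroni <- function(p_values, alpha = 0.05) {
  m <- sum(is.finite(p_values))
  if (m < 1) stopf("no finite p-values")
  threshold <- alpha / m
  sig <- is.finite(p_values) & p_values <= threshold
  list(threshold = threshold, significant = sig, m = m)
}

#' Genomic-control inflation factor (robust median estimator)
#'
#' Converts the median p-value to a 1-df chi-square quantile and divides by
#' the null median `qchisq(0.5, 1) = 0.4549...`. A value of 1 indicates
#' calibration; values above 1 indicate inflation.
#'
#' @param p_values Numeric vector of p-values (NAs dropped).
#' @return The inflation factor lambda.
#' @export
genomic_lambda <- function(p_values) {
  p <- p_values[is.finite(p_values)]
  if (!length(p)) stopf("no finite p-values")
  stats::qchisq(1 - stats::median(p), df = 1) / stats::qchisq(0.5, df = 1)
}

#' QQ-plot data with a 95% pointwise null band
#'
#' Observed order statistics of -log10(p) paired with the -log10 of uniform
#' order-statistic medians, plus a pointwise 95% band from the
#' Beta(i, n - i + 1) distribution of uniform order statistics.
#'
#' @param p_values Numeric vector of p-values (NAs dropped).
#' @return data.frame with columns `expected`, `observed`, `lower`, `upper`
#'   (all on the -log10 scale), sorted from least to most significant.
#' @export
qq_data <- function(p_values) {
  p <- sort(p_values[is.finite(p_values)], decreasing = TRUE)
  n <- length(p)
  if (!n) stopf("no finite p-values")
  i <- n:1  # rank of each sorted p-value, largest p = rank n
  data.frame(expected = -log10(stats::qbeta(0.5, i, n - i + 1)),
             observed = -log10(p),
             lower = -log10(stats::qbeta(0.975, i, n - i + 1)),
             upper = -log10(stats::qbeta(0.025, i, n - i + 1)))
}

#' Calibration diagnostics for a results table
#'
#' Computes genomic-control lambdas and QQ data for both tests from a
#' results table (data.frame or TSV path), optionally writing plot-ready
#' TSVs.
#'
#' @param results Results data.frame or path to a results TSV.
#' @param out Optional output directory for `qq_drab.tsv`, `qq_cond.tsv`,
#'   `lambda.tsv`.
#' @return List with `lambda_drab`, `lambda_cond`, `qq_drab`, `qq_cond`.
#' @export
drab_diagnose <- function(results, out = NULL) {
  if (is.character(results)) results <- read_results(results)
  res <- list(lambda_drab = genomic_lambda(results$p_drab),
              lambda_cond = genomic_lambda(results$p_conditional),
              qq_drab = qq_data(results$p_drab),
              qq_cond = qq_data(results$p_conditional))
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(res$qq_drab, file.path(out, "qq_drab.tsv"), sep = "\t")
    data.table::fwrite(res$qq_cond, file.path(out, "qq_cond.tsv"), sep = "\t")
    data.table::fwrite(data.frame(test = c("drab", "conditional"),
                                  lambda = c(res$lambda_drab, res$lambda_cond)),
                       file.path(out, "lambda.tsv"), sep = "\t")
  }
  res
}
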
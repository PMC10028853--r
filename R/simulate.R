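# Synthetic cohorts with the statistical structure the method assumes:
# binomial dosage genotypes at given minor-allele frequencies (optionally
# with haplotype-copying LD), sparse per-context cis effect vectors, and
# additive Gaussian expression noise. The generator writes the exact
# on-disk formats the pipeline consumes plus a truth table sufficient for
# exact null/alternative labeling.

#' Simulate dosage genotypes
#'
#' Dosages are drawn Binomial(2, maf_j) independently per sample. With
#' `ld_rho > 0`, two latent haplotypes per individual are generated by a
#' copying process in which each site copies the previous site's allele
#' with probability `ld_rho`, producing adjacent-variant correlation close
#' to `ld_rho`.
#'
#' @param n,p Numbers of samples and variants.
#' @param maf Minor allele frequency (scalar or length-p vector) in
#'   (0, 0.5].
#' @param seed Integer seed.
#' @param ld_rho Haplotype-copying probability in \[0, 1) (default 0 =
#'   linkage equilibrium).
#' @param chrom Chromosome code for the variant records (default "1").
#' @param pos Base-pair positions (default 1..p).
#' @param ids Variant ids (default snp1..snpp).
#' @param sample_ids Sample ids (default s1..sn).
#' @return A [genotype_matrix()].
#' @export
sim_genotypes <- function(n, p, maf = 0.3, seed = 1, ld_rho = 0, chrom = "1",
                          pos = NULL, ids = NULL, sample_ids = NULL) {
  if (n < 1 || p < 1) stopf("n and p must be at least 1")
  maf <- rep_len(maf, p)
  if (any(maf <= 0 | maf > 0.5)) stopf("maf must lie in (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stopf("ld_rho must lie in [0, 1)")
  dos <- with_seed(seed, {
    if (ld_rho == 0) {
      matrix(stats::rbinom(n * p, 2L, rep(maf, each = n)), n, p)
    } else {
      hap <- function() {
        h <- matrix(0L, n, p)
        h[, 1] <- stats::rbinom(n, 1L, maf[1])
        for (j in seq_len(p)[-1]) {
          copy <- stats::rbinom(n, 1L, ld_rho)
          h[, j] <- ifelse(copy == 1L, h[, j - 1], stats::rbinom(n, 1L, maf[j]))
        }
        h
      }
      hap() + hap()
    }
  })
  genotype_matrix(dos,
                  sample_ids %||% paste0("s", seq_len(n)),
                  data.frame(id = ids %||% paste0("snp", seq_len(p)),
                             chrom = chrom,
                             pos = pos %||% seq_len(p),
                             allele1 = "A", allele2 = "G",
                             stringsAsFactors = FALSE))
}

#' Simulate expression from genotypes
#'
#' `y = G beta + eps` with `eps ~ Normal(0, noise_var)` i.i.d.; the noise
#' represents non-genetic effects on expression and its variance is
#' parameterized directly.
#'
#' @param G A [genotype_matrix()].
#' @param beta Effect vector aligned to the columns of `G`.
#' @param noise_var Gaussian noise variance (> 0).
#' @param seed Integer seed.
#' @return Named numeric expression vector.
#' @export
sim_expression <- function(G, beta, noise_var = 1, seed = 1) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (noise_var <= 0) stopf("noise_var must be positive")
  if (length(beta) != ncol(G$dosages))
    stopf("beta length %d does not match %d variants", length(beta), ncol(G$dosages))
  n <- nrow(G$dosages)
  y <- drop(G$dosages %*% beta) +
    with_seed(seed, stats::rnorm(n, 0, sqrt(noise_var)))
  stats::setNames(y, G$sample_ids)
}

#' Generate a complete on-disk scenario
#'
#' Writes an immediately runnable input set: PLINK genotypes for all genes'
#' cis regions, per-context expression matrices, covariates, gene
#' annotations, a gene list, and a truth TSV recording each gene's causal
#' variants and effect sizes.
#'
#' In a `"null"` scenario the two contexts share one effect vector and one
#' measured expression matrix (the single-cohort negative-control design:
#' any split of the samples into contexts is null by construction). In a
#' `"differential"` scenario each context has its own causal set (sharing a
#' configurable fraction, default disjoint) and its own expression draw.
#'
#' Each gene occupies its own non-overlapping cis region; covariates enter
#' expression additively and are removed again by the pipeline's
#' residualization step.
#'
#' @param dir Output directory (created if needed).
#' @param kind `"null"` or `"differential"`.
#' @param n_genes Number of genes (default 20).
#' @param n Number of samples (default 300).
#' @param p Cis-SNPs per gene (default 50).
#' @param n_causal Causal SNPs per context per gene (default 5).
#' @param h2 Fraction of expression variance explained by genotype in each
#'   context (default 0.2); effects are rescaled on the realized genotypes
#'   so the genetic variance is exactly `h2` and the Gaussian noise variance
#'   is `1 - h2`.
#' @param causal_overlap Fraction of causal SNPs shared between contexts in
#'   a differential scenario (default 0 = disjoint sets).
#' @param maf_range Range minor allele frequencies are drawn from
#'   (default c(0.05, 0.5)).
#' @param ld_rho Haplotype-copying LD parameter (default 0).
#' @param n_covariates Number of additive nuisance covariates (default 2).
#' @param seed Master seed.
#' @return List with `paths` (named file paths: bfile, expr_a, expr_b,
#'   covar, annot, genes, truth) and `truth` (the truth data.frame).
#' @export
make_scenario <- function(dir, kind = c("null", "differential"),
                          n_genes = 20, n = 300, p = 50, n_causal = 5,
                          h2 = 0.2, causal_overlap = 0,
                          maf_range = c(0.05, 0.5), ld_rho = 0,
                          n_covariates = 2, seed = 1) {
  kind <- match.arg(kind)
  if (n_causal > p) stopf("n_causal (%d) cannot exceed p (%d)", n_causal, p)
  if (h2 <= 0 || h2 >= 1) stopf("h2 must lie in (0, 1)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sample_ids <- sprintf("s%04d", seq_len(n))

  covar <- with_seed(derive_seed(seed, "covariates"),
                     matrix(stats::rnorm(n * n_covariates), n, n_covariates,
                            dimnames = list(sample_ids,
                                            paste0("PC", seq_len(n_covariates)))))

  genos <- vector("list", n_genes)
  expr_a <- matrix(NA_real_, n_genes, n, dimnames = list(NULL, sample_ids))
  expr_b <- expr_a
  annot <- data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
                      chrom = as.character(((seq_len(n_genes) - 1) %% 22) + 1),
                      tss = NA_real_, tes = NA_real_, strand = "+")
  truth <- vector("list", n_genes)
  noise_var <- 1 - h2

  for (g in seq_len(n_genes)) {
    slot <- (g - 1) %/% 22
    tss <- 1e6 + slot * 2.4e6
    tes <- tss + 1e4
    annot$tss[g] <- tss
    annot$tes[g] <- tes
    maf <- with_seed(derive_seed(seed, "maf", g),
                     stats::runif(p, maf_range[1], maf_range[2]))
    pos <- with_seed(derive_seed(seed, "pos", g),
                     sort(sample.int(9e5, p)) + tss - 4.5e5)
    Gg <- sim_genotypes(n, p, maf, seed = derive_seed(seed, "geno", g),
                        ld_rho = ld_rho, chrom = annot$chrom[g], pos = pos,
                        ids = sprintf("%s_snp%03d", annot$gene_id[g], seq_len(p)),
                        sample_ids = sample_ids)
    genos[[g]] <- Gg

    eff <- with_seed(derive_seed(seed, "effects", g), {
      ca <- sample.int(p, n_causal)
      n_shared <- round(causal_overlap * n_causal)
      shared <- ca[seq_len(n_shared)]
      cb_new <- sample(setdiff(seq_len(p), ca), n_causal - n_shared)
      cb <- c(shared, cb_new)
      list(ca = ca, cb = if (kind == "null") ca else cb,
           ba = stats::rnorm(n_causal), bb = stats::rnorm(n_causal))
    })
    scale_to_h2 <- function(idx, raw) {
      beta <- numeric(p)
      beta[idx] <- raw
      gv <- stats::var(drop(Gg$dosages %*% beta))
      if (gv > 0) beta <- beta * sqrt(h2 / gv)
      beta
    }
    beta_a <- scale_to_h2(eff$ca, eff$ba)
    beta_b <- if (kind == "null") beta_a else scale_to_h2(eff$cb, eff$bb)

    gamma <- with_seed(derive_seed(seed, "coveff", g),
                       stats::rnorm(n_covariates, 0, sqrt(0.1 / max(n_covariates, 1))))
    cov_part <- if (n_covariates > 0) drop(covar %*% gamma) else 0
    ya <- sim_expression(Gg, beta_a, noise_var,
                         seed = derive_seed(seed, "noise-a", g)) + cov_part
    yb <- if (kind == "null") ya else
      sim_expression(Gg, beta_b, noise_var,
                     seed = derive_seed(seed, "noise-b", g)) + cov_part
    expr_a[g, ] <- ya
    expr_b[g, ] <- yb

    truth[[g]] <- data.frame(
      gene_id = annot$gene_id[g], kind = kind,
      causal_ids_a = paste(Gg$variants$id[eff$ca], collapse = ","),
      causal_ids_b = paste(Gg$variants$id[eff$cb], collapse = ","),
      effects_a = paste(signif(beta_a[eff$ca], 6), collapse = ","),
      effects_b = paste(signif(beta_b[eff$cb], 6), collapse = ","),
      h2 = h2, noise_var = noise_var, stringsAsFactors = FALSE)
  }

  G_all <- genos[[1]]
  if (n_genes > 1) {
    G_all <- genotype_matrix(
      do.call(cbind, lapply(genos, function(g) g$dosages)),
      sample_ids,
      do.call(rbind, lapply(genos, function(g) g$variants)))
  }

  paths <- list(bfile = file.path(dir, "geno"),
                expr_a = file.path(dir, "expr_a.tsv"),
                expr_b = file.path(dir, "expr_b.tsv"),
                covar = file.path(dir, "covariates.tsv"),
                annot = file.path(dir, "annotation.tsv"),
                genes = file.path(dir, "genes.txt"),
                truth = file.path(dir, "truth.tsv"))
  write_plink(G_all, paths$bfile)
  write_expression(expression_matrix(expr_a, annot$gene_id, sample_ids),
                   paths$expr_a)
  write_expression(expression_matrix(expr_b, annot$gene_id, sample_ids),
                   paths$expr_b)
  data.table::fwrite(data.frame(sample_id = sample_ids, covar,
                                check.names = FALSE),
                     paths$covar, sep = "\t")
  data.table::fwrite(annot, paths$annot, sep = "\t")
  writeLines(annot$gene_id, paths$genes)
  truth <- do.call(rbind, truth)
  data.table::fwrite(truth, paths$truth, sep = "\t")
  list(paths = paths, truth = truth)
}
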
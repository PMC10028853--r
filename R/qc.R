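# Variant-level quality control: minor allele frequency, exact
# Hardy-Weinberg equilibrium (Levene-Haldane) with the mid-p adjustment,
# and the combined autosome / allele-code / missingness / HWE / MAF filter.

#' Minor allele frequency of a dosage vector
#'
#' @param x Dosage vector with entries in \{0, 1, 2\} (no missing values).
#' @return `min(f, 1 - f)` where `f = mean(x) / 2`; always in [0, 0.5].
#' @export
minor_allele_frequency <- function(x) {
  if (!length(x)) stopf("empty dosage vector")
  if (anyNA(x)) stopf("dosage vector contains missing calls")
  f <- mean(x) / 2
  min(f, 1 - f)
}

#' Genotype counts of a dosage vector
#' @param x Dosage vector in \{0, 1, 2\}.
#' @return Integer vector `c(n_hom_a1, n_het, n_hom_a2)` counting dosage-2,
#'   dosage-1, and dosage-0 samples.
#' @export
genotype_counts <- function(x) {
  if (anyNA(x)) stopf("dosage vector contains missing calls")
  c(n_hom_a1 = sum(x == 2), n_het = sum(x == 1), n_hom_a2 = sum(x == 0))
}

# Conditional distribution of the heterozygote count given the minor-allele
# count, via the Levene-Haldane recurrence. Returns a named numeric vector
# over all attainable heterozygote counts (same parity as the rare-allele
# count). Used by hwe_midp; the tests check it against a direct
# combinatorial enumeration.
het_count_distribution <- function(n_rare, n_genotypes) {
  n_common <- 2L * n_genotypes - n_rare
  h_max <- min(n_rare, n_common)
  h <- seq.int(n_rare %% 2L, h_max, by = 2L)
  probs <- numeric(length(h))
  # start at the (approximate) mode and recur outward for stability
  mid <- round(n_rare * n_common / (2 * n_genotypes))
  if (mid %% 2L != n_rare %% 2L) mid <- mid + 1L
  mid <- min(max(mid, h[1]), h[length(h)])
  i0 <- match(mid, h)
  probs[i0] <- 1
  if (i0 < length(h)) {
    for (i in i0:(length(h) - 1L)) {
      hh <- h[i]
      probs[i + 1L] <- probs[i] * (n_rare - hh) * (n_common - hh) /
        ((hh + 2) * (hh + 1))
    }
  }
  if (i0 > 1L) {
    for (i in i0:2L) {
      hh <- h[i]
      probs[i - 1L] <- probs[i] * hh * (hh - 1) /
        ((n_rare - hh + 2) * (n_common - hh + 2))
    }
  }
  probs <- probs / sum(probs)
  names(probs) <- h
  probs
}

#' Exact Hardy-Weinberg equilibrium test with mid-p adjustment
#'
#' Levene-Haldane exact test: conditions on the observed allele counts and
#' enumerates the distribution of the heterozygote count. The two-sided
#' p-value sums the probabilities of all heterozygote counts whose
#' probability does not exceed that of the observed count; the mid-p
#' adjustment then subtracts half the observed count's probability.
#'
#' @param counts Either an integer vector `c(n_hom_a1, n_het, n_hom_a2)` or
#'   the three counts as separate arguments via `...`.
#' @param ... Optional `n_het`, `n_hom_a2` when `counts` is given as a
#'   scalar first count.
#' @return Mid-p value in (0, 1].
#' @export
hwe_midp <- function(counts, ...) {
  extra <- c(...)
  if (length(extra)) counts <- c(counts, extra)
  if (length(counts) != 3) stopf("need exactly three genotype counts")
  if (any(counts < 0)) stopf("genotype counts must be non-negative")
  if (any(counts != round(counts))) stopf("genotype counts must be integers")
  n <- sum(counts)
  if (n < 1) stopf("total genotype count must be positive")
  n_het <- counts[2]
  n_rare <- min(2 * counts[1] + n_het, 2 * counts[3] + n_het)
  probs <- het_count_distribution(as.integer(n_rare), as.integer(n))
  p_obs <- probs[[as.character(n_het)]]
  # relative slack so that structurally tied tables are always included
  p_exact <- sum(probs[probs <= p_obs * (1 + 1e-10)])
  max(min(p_exact - 0.5 * p_obs, 1), .Machine$double.xmin)
}

QC_FILTERS <- c("non_autosomal", "allele_code", "missing", "hwe", "maf")

#' Apply variant quality control
#'
#' Sequentially removes variants that are (1) non-autosomal (chromosome
#' codes outside 1-22), (2) carry a multi-character or nonstandard allele
#' code (anything but A/C/G/T), (3) have one or more missing calls, (4) fail
#' the exact HWE mid-p test at `hwe_p_min`, or (5) have minor allele
#' frequency below `maf_min`. Filters are independent per-variant
#' predicates, so the surviving set does not depend on their order; the
#' removal report follows the order above.
#'
#' @param G A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.01); variants
#'   with MAF strictly below it are removed.
#' @param hwe_p_min HWE mid-p threshold (default 1e-6); variants with
#'   mid-p < `hwe_p_min` are removed.
#' @param log_path Optional path: the per-filter removal report is written
#'   there as TSV.
#' @return Filtered [genotype_matrix()] with a `qc_log` attribute
#'   (data.frame filter/removed).
#' @export
apply_variant_qc <- function(G, maf_min = 0.01, hwe_p_min = 1e-6, log_path = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (maf_min < 0 || maf_min > 1 || hwe_p_min < 0 || hwe_p_min > 1)
    stopf("QC thresholds must lie in [0, 1]")

  keep <- rep(TRUE, nrow(G$variants))
  removed <- integer(length(QC_FILTERS))
  names(removed) <- QC_FILTERS

  autosomal <- G$variants$chrom %in% as.character(1:22)
  removed["non_autosomal"] <- sum(keep & !autosomal)
  keep <- keep & autosomal

  std <- grepl("^[ACGTacgt]$", G$variants$allele1) &
    grepl("^[ACGTacgt]$", G$variants$allele2)
  removed["allele_code"] <- sum(keep & !std)
  keep <- keep & std

  n_missing <- pmax(G$variants$n_missing, colSums(is.na(G$dosages)))
  complete <- n_missing == 0
  removed["missing"] <- sum(keep & !complete)
  keep <- keep & complete

  hwe_ok <- rep(TRUE, length(keep))
  for (j in which(keep)) {
    hwe_ok[j] <- hwe_midp(genotype_counts(G$dosages[, j])) >= hwe_p_min
  }
  removed["hwe"] <- sum(keep & !hwe_ok)
  keep <- keep & hwe_ok

  maf_ok <- rep(TRUE, length(keep))
  for (j in which(keep)) {
    maf_ok[j] <- minor_allele_frequency(G$dosages[, j]) >= maf_min
  }
  removed["maf"] <- sum(keep & !maf_ok)
  keep <- keep & maf_ok

  if (!any(keep)) {
    stopf("variant QC removed every variant (non_autosomal=%d, allele_code=%d, missing=%d, hwe=%d, maf=%d)",
          removed["non_autosomal"], removed["allele_code"], removed["missing"],
          removed["hwe"], removed["maf"])
  }

  log <- data.frame(filter = QC_FILTERS, removed = as.integer(removed))
  if (!is.null(log_path)) data.table::fwrite(log, log_path, sep = "\t")
  out <- subset_variants(G, keep)
  attr(out, "qc_log") <- log
  out
}
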
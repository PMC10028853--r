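#' Construct a genotype matrix
#'
#' The canonical in-memory container for individual-level genotypes: a
#' samples-by-variants matrix of allele dosages in \{0, 1, 2\} (possibly `NA`
#' for missing calls, which variant QC removes) together with per-variant
#' metadata.
#'
#' @param dosages Numeric matrix, rows = samples, columns = variants, entries
#'   in \{0, 1, 2\} or `NA` for a missing call. Dosage counts copies of
#'   `allele1` (the first allele column of the BIM file when read from PLINK;
#'   orientation is immaterial downstream because genotypes are standardized
#'   per split, but it is fixed here for reproducibility).
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row of `dosages`.
#' @param variants A data.frame with one row per column of `dosages` and
#'   columns `id`, `chrom`, `pos`, `allele1`, `allele2`. A `n_missing`
#'   column (missing-call count per variant) is added if absent.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `sample_ids`, `variants`.
#' @export
genotype_matrix <- function(dosages, sample_ids, variants) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  sample_ids <- as.character(sample_ids)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)

  if (nrow(dosages) != length(sample_ids))
    stopf("dosage matrix has %d rows but %d sample ids", nrow(dosages), length(sample_ids))
  if (ncol(dosages) != nrow(variants))
    stopf("dosage matrix has %d columns but %d variant records", ncol(dosages), nrow(variants))
  if (anyDuplicated(sample_ids))
    stopf("sample ids must be unique")
  need <- c("id", "chrom", "pos", "allele1", "allele2")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stopf("variant table lacks columns: %s", paste(miss, collapse = ", "))
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stopf("dosages must be 0, 1, 2, or NA")
  if (!"n_missing" %in% names(variants))
    variants$n_missing <- as.integer(colSums(is.na(dosages)))

  variants$id <- as.character(variants$id)
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.numeric(variants$pos)
  rownames(dosages) <- sample_ids
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages, sample_ids = sample_ids, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (%d with missing calls)\n",
              length(x$sample_ids), nrow(x$variants), sum(x$variants$n_missing > 0)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# Column (variant) subset preserving order; j is logical or integer.
subset_variants <- function(G, j) {
  genotype_matrix(G$dosages[, j, drop = FALSE], G$sample_ids,
                  G$variants[j, , drop = FALSE])
}

# Row (sample) subset by index or id.
subset_samples <- function(G, i) {
  if (is.character(i)) i <- match(i, G$sample_ids)
  if (anyNA(i)) stopf("unknown sample ids in subset")
  genotype_matrix(G$dosages[i, , drop = FALSE], G$sample_ids[i], G$variants)
}
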
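# Tab-separated IO for expression, covariates, gene annotations, gene lists,
# and the per-gene results table.

#' Read a gene expression matrix
#'
#' Expects a TSV whose first column holds gene identifiers and whose header
#' names the samples; one row per gene.
#'
#' @param path Path to the TSV file.
#' @return An object of class `expression_matrix`: list with `values`
#'   (genes x samples numeric matrix), `gene_ids`, `sample_ids`.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stopf("expression file not found: %s", path)
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (ncol(tab) < 2) stopf("expression file needs a gene-id column plus samples: %s", path)
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids))
    stopf("duplicated gene ids in %s: %s", path,
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(num <- as.numeric(vals[[j]]))
      bad <- which(is.na(num) & !(vals[[j]] %in% c("NA", "")))
      if (length(bad))
        stopf("non-numeric expression value at gene '%s', sample '%s' in %s",
              gene_ids[bad[1]], names(vals)[j], path)
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  if (any(!is.finite(m)))
    stopf("expression matrix contains non-finite values: %s", path)
  expression_matrix(m, gene_ids, colnames(m))
}

#' Construct an expression matrix
#'
#' @param values Genes x samples numeric matrix.
#' @param gene_ids,sample_ids Row and column identifiers.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, gene_ids, sample_ids) {
  values <- as.matrix(values)
  if (anyDuplicated(gene_ids)) stopf("gene ids must be unique")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stopf("expression dimensions do not match id vectors")
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids)),
            class = "expression_matrix")
}

#' Write an expression matrix as TSV
#' @param E An [expression_matrix()].
#' @param path Output path.
#' @export
write_expression <- function(E, path) {
  stopifnot(inherits(E, "expression_matrix"))
  out <- data.frame(gene_id = E$gene_ids, E$values, check.names = FALSE)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a covariate table
#'
#' TSV with the first column holding sample ids and remaining columns holding
#' numeric covariates (e.g. genotype principal components, batch indicators).
#'
#' @param path Path to the TSV file.
#' @return A `covariate_matrix`: list with `values` (samples x covariates),
#'   `sample_ids`, `covariate_names`.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stopf("covariate file not found: %s", path)
  tab <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  sample_ids <- as.character(tab[[1]])
  if (anyDuplicated(sample_ids)) stopf("duplicated sample ids in %s", path)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (any(!is.finite(vals))) stopf("covariates contain non-finite values: %s", path)
  structure(list(values = vals, sample_ids = sample_ids,
                 covariate_names = colnames(vals)),
            class = "covariate_matrix")
}

#' Read gene annotations
#'
#' Accepts a TSV with columns `gene_id`, `chrom`, `tss`, `tes` (and optional
#' `strand`), with or without a header line. Coordinates are 1-based
#' inclusive. TSS/TES are canonicalized so that `tss <= tes` regardless of
#' strand; the cis window is symmetric, so strand never changes it.
#'
#' @param path Path to the annotation file.
#' @return A data.frame with columns `gene_id`, `chrom`, `tss`, `tes`,
#'   `strand`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("gene_id", first, fixed = TRUE)
  tab <- data.table::fread(path, sep = "\t", header = has_header, data.table = FALSE)
  if (ncol(tab) < 4) stopf("annotation needs >= 4 columns (gene_id, chrom, tss, tes): %s", path)
  names(tab)[1:4] <- c("gene_id", "chrom", "tss", "tes")
  if (ncol(tab) >= 5) names(tab)[5] <- "strand" else tab$strand <- "+"
  tab$gene_id <- as.character(tab$gene_id)
  tab$chrom <- as.character(tab$chrom)
  tab$tss <- as.numeric(tab$tss)
  tab$tes <- as.numeric(tab$tes)
  flip <- tab$tss > tab$tes
  if (any(flip)) {
    tmp <- tab$tss[flip]
    tab$tss[flip] <- tab$tes[flip]
    tab$tes[flip] <- tmp
  }
  tab[, c("gene_id", "chrom", "tss", "tes", "strand")]
}

#' Read a gene list (one id per line)
#' @param path Path to the list file.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stopf("gene list not found: %s", path)
  ids <- readLines(path)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

RESULT_COLUMNS <- c("gene_id", "n_train", "n_test", "delta_loss", "t_drab",
                    "df", "p_drab", "p_conditional", "n_snps_selected_A",
                    "n_snps_selected_B", "status")

#' Write per-gene test results as TSV
#'
#' Columns, in fixed order: gene_id, n_train, n_test, delta_loss, t_drab, df,
#' p_drab, p_conditional, n_snps_selected_A, n_snps_selected_B, status.
#' P-values are serialized at full double precision.
#'
#' @param results A non-empty list of results from [test_gene()], or a
#'   data.frame already in results-table form.
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  tab <- results_table(results)
  data.table::fwrite(tab, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Assemble a results data.frame from a list of per-gene results
#' @param results List of `drab_result` objects or a data.frame.
#' @return data.frame with the canonical column order.
#' @export
results_table <- function(results) {
  if (is.data.frame(results)) {
    miss <- setdiff(RESULT_COLUMNS, names(results))
    if (length(miss)) stopf("results table lacks columns: %s", paste(miss, collapse = ", "))
    return(results[, RESULT_COLUMNS])
  }
  if (!length(results)) stopf("no results to write")
  do.call(rbind, lapply(results, as.data.frame))
}

#' Read back a results TSV written by [write_results()]
#' @param path Path to the results file.
#' @return data.frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stopf("results file not found: %s", path)
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}
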
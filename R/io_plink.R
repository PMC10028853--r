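# PLINK 1 binary genotype IO.
#
# The .bed format stores genotypes variant-major, 2 bits per sample, four
# samples per byte, least-significant bits first, preceded by the magic
# bytes 0x6c 0x1b and the mode byte 0x01. Two-bit codes: 00 = homozygous
# allele1 (dosage 2), 01 = missing, 10 = heterozygous (dosage 1),
# 11 = homozygous allele2 (dosage 0).

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b))
PLINK_SNP_MAJOR <- as.raw(0x01)
# dosage of allele1 indexed by 2-bit code + 1
PLINK_CODE_TO_DOSAGE <- c(2, NA, 1, 0)

#' Read a PLINK BED/BIM/FAM triplet
#'
#' Loads individual-level genotypes from the PLINK 1 binary format into a
#' [genotype_matrix()]. Dosages count copies of the BIM file's first allele
#' (`allele1`, conventionally the minor allele in PLINK 1.9 output). Missing
#' calls are kept as `NA` and counted per variant in the `n_missing` column
#' of the variant table; [apply_variant_qc()] removes any variant with one
#' or more missing calls before modeling.
#'
#' @param prefix Path prefix; `prefix.bed`, `prefix.bim`, `prefix.fam` must
#'   all exist.
#' @return A [genotype_matrix()] with samples ordered as in the .fam file and
#'   variants ordered as in the .bim file.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (pth in paths)
    if (!file.exists(pth)) stopf("PLINK file not found: %s", pth)

  bim <- data.table::fread(paths[2], header = FALSE, colClasses = "character",
                           data.table = FALSE)
  if (ncol(bim) < 6) stopf("malformed .bim file (expected 6 columns): %s", paths[2])
  names(bim)[1:6] <- c("chrom", "id", "cm", "pos", "allele1", "allele2")
  fam <- data.table::fread(paths[3], header = FALSE, colClasses = "character",
                           data.table = FALSE)
  if (ncol(fam) < 2) stopf("malformed .fam file: %s", paths[3])
  sample_ids <- fam[[2]]
  if (anyDuplicated(sample_ids)) sample_ids <- paste(fam[[1]], fam[[2]], sep = ":")

  n <- length(sample_ids)
  p <- nrow(bim)
  bytes_per_variant <- ceiling(n / 4)
  raw <- readBin(paths[1], what = "raw", n = file.info(paths[1])$size)
  if (length(raw) < 3 || !identical(raw[1:2], PLINK_MAGIC))
    stopf("not a PLINK .bed file (bad magic bytes): %s", paths[1])
  if (!identical(raw[3], PLINK_SNP_MAJOR))
    stopf("only SNP-major (variant-major) .bed files are supported: %s", paths[1])
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_variant * p)
    stopf(".bed payload has %d bytes; expected %d for %d samples x %d variants",
          length(body), bytes_per_variant * p, n, p)

  ints <- as.integer(body)
  dosages <- matrix(NA_real_, n, p)
  for (k in 0:3) {
    rows <- seq.int(k + 1L, by = 4L, length.out = bytes_per_variant)
    keep <- rows <= n
    if (!any(keep)) next
    codes <- bitwAnd(bitwShiftR(ints, 2L * k), 3L)
    vals <- matrix(PLINK_CODE_TO_DOSAGE[codes + 1L], bytes_per_variant, p)
    dosages[rows[keep], ] <- vals[keep, , drop = FALSE]
  }

  variants <- data.frame(id = bim$id, chrom = bim$chrom,
                         pos = as.numeric(bim$pos),
                         allele1 = bim$allele1, allele2 = bim$allele2,
                         stringsAsFactors = FALSE)
  genotype_matrix(dosages, sample_ids, variants)
}

#' Write a genotype matrix as a PLINK BED/BIM/FAM triplet
#'
#' Inverse of [read_plink()]: round-tripping through disk is the identity on
#' dosages, sample ids, and variant metadata (centimorgan positions are
#' written as 0).
#'
#' @param G A [genotype_matrix()].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  n <- length(G$sample_ids)
  p <- nrow(G$variants)

  fam <- data.frame(fid = G$sample_ids, iid = G$sample_ids,
                    pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  data.table::fwrite(fam, paste0(prefix, ".fam"), sep = "\t", col.names = FALSE)
  bim <- data.frame(chrom = G$variants$chrom, id = G$variants$id, cm = 0L,
                    pos = format(G$variants$pos, scientific = FALSE, trim = TRUE),
                    allele1 = G$variants$allele1, allele2 = G$variants$allele2)
  data.table::fwrite(bim, paste0(prefix, ".bim"), sep = "\t", col.names = FALSE)

  # dosage -> 2-bit code: 2 -> 00, 1 -> 10, 0 -> 11, NA -> 01
  code <- matrix(0L, n, p)
  d <- G$dosages
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 1] <- 2L
  code[!is.na(d) & d == 0] <- 3L

  bytes_per_variant <- ceiling(n / 4)
  padded <- matrix(0L, bytes_per_variant * 4L, p)
  padded[seq_len(n), ] <- code
  bytes <- integer(bytes_per_variant * p)
  for (k in 0:3) {
    rows <- seq.int(k + 1L, by = 4L, length.out = bytes_per_variant)
    bytes <- bytes + bitwShiftL(as.integer(padded[rows, , drop = FALSE]), 2L * k)
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(c(PLINK_MAGIC, PLINK_SNP_MAJOR, as.raw(bytes)), con)
  invisible(prefix)
}
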
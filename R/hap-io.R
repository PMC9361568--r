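#' Write a haplotype matrix as a plain TSV
#'
#' Rows are sites, columns `chrom`, `pos`, then one 0/1 column per
#' haplotype (named `sample.hap`).
#'
#' @param hapmat A [hap_matrix()].
#' @param path Output file.
#' @export
write_hap_tsv <- function(hapmat, path) {
  d <- data.frame(chrom = attr(hapmat, "chrom"), pos = attr(hapmat, "positions"),
                  unclass(hapmat), check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a haplotype matrix from TSV
#' @param path File produced by [write_hap_tsv()].
#' @return A [hap_matrix()].
#' @export
read_hap_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  m <- as.matrix(d[, -(1:2), drop = FALSE])
  hap_matrix(m, positions = d$pos, chrom = as.character(d$chrom[1L]))
}

#' Write phased haplotypes as a minimal VCF
#'
#' Emits a VCFv4.2 file with phased `GT` fields (`0|1` style), pairing
#' consecutive haplotype columns into diploid samples. The reference allele
#' is `A` and the alternate `T` at every site (alleles in this package are
#' abstract 0 = ancestral / 1 = derived labels).
#'
#' @param hapmat A [hap_matrix()] with an even number of columns.
#' @param path Output file.
#' @param samples Optional diploid sample names (default derived from
#'   column names or `S1..Sn`).
#' @export
write_phased_vcf <- function(hapmat, path, samples = NULL) {
  n_hap <- ncol(hapmat)
  if (n_hap %% 2L != 0L) stop("need an even number of haplotypes to form diploids")
  n <- n_hap %/% 2L
  if (is.null(samples)) {
    cn <- colnames(hapmat)
    samples <- if (!is.null(cn)) unique(sub("\\.[01]$", "", cn)) else sprintf("S%d", seq_len(n))
    if (length(samples) != n) samples <- sprintf("S%d", seq_len(n))
  }
  pos <- attr(hapmat, "positions")
  gt <- matrix(paste(hapmat[, seq(1L, n_hap, 2L), drop = FALSE],
                     hapmat[, seq(2L, n_hap, 2L), drop = FALSE], sep = "|"),
               nrow = nrow(hapmat))
  body <- paste(attr(hapmat, "chrom"), format(pos, scientific = FALSE, trim = TRUE),
                ".", "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body), path)
  invisible(path)
}

#' Read phased haplotypes from a VCF
#'
#' Thin wrapper over the `vcfR` parser: extracts phased GT fields and
#' splits each diploid sample into two haplotype columns (`sample.0`,
#' `sample.1`).
#'
#' @param path VCF file.
#' @return A [hap_matrix()].
#' @export
read_phased_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(!grepl("|", gt, fixed = TRUE))) stop("VCF genotypes are not phased")
  left <- matrix(as.integer(sub("\\|.*", "", gt)), nrow = nrow(gt))
  right <- matrix(as.integer(sub(".*\\|", "", gt)), nrow = nrow(gt))
  out <- matrix(0L, nrow = nrow(gt), ncol = 2L * ncol(gt))
  out[, seq(1L, ncol(out), 2L)] <- left
  out[, seq(2L, ncol(out), 2L)] <- right
  colnames(out) <- paste0(rep(colnames(gt), each = 2L), ".", rep(0:1, ncol(gt)))
  hap_matrix(out, positions = as.numeric(v@fix[, "POS"]),
             chrom = as.character(v@fix[1L, "CHROM"]))
}
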
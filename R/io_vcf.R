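#' Read phased haplotypes from a VCF file
#'
#' Reads a biallelic, fully phased VCF (as produced by phasing tools such as
#' Beagle) into a binary haplotype matrix with two rows per sample, in file
#' order. Parsing is delegated to \pkg{vcfR}; this function enforces the
#' haplotype-set contract: every record biallelic, every GT `"|"`-phased and
#' complete.
#'
#' @param vcf_path Path to an uncompressed or gzipped VCF.
#' @return A list with `haps` (integer matrix, rows `<sample>_h1/_h2`) and
#'   `loci` (data frame: `chrom`, `snp`, `pos`, `allele_a` = REF,
#'   `allele_b` = ALT, `autosomal`).
#' @export
read_phased_vcf <- function(vcf_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- sprintf("var%d", which(is.na(ids) | ids == "."))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    stop("multiallelic record(s) not supported: ",
         paste(utils::head(ids[multi], 5L), collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop("unphased genotypes ('/' separator) found; ",
         "phase the VCF externally (e.g. with Beagle) before loading")
  }
  if (anyNA(gt) || !all(gt %in% c("0|0", "0|1", "1|0", "1|1"))) {
    stop("all GT fields must be complete, phased and biallelic (e.g. '0|1')")
  }
  n <- ncol(gt)
  m <- nrow(gt)
  haps <- matrix(0L, 2L * n, m)
  h1 <- t(matrix(as.integer(substr(gt, 1L, 1L)), m, n))
  h2 <- t(matrix(as.integer(substr(gt, 3L, 3L)), m, n))
  haps[seq(1L, 2L * n, by = 2L), ] <- h1
  haps[seq(2L, 2L * n, by = 2L), ] <- h2
  rownames(haps) <- paste0(rep(colnames(gt), each = 2L), c("_h1", "_h2"))

  loci <- data.frame(chrom = fix[, "CHROM"], snp = ids,
                     pos = as.numeric(fix[, "POS"]),
                     allele_a = fix[, "REF"], allele_b = fix[, "ALT"],
                     autosomal = NA, stringsAsFactors = FALSE)
  colnames(haps) <- loci$snp
  list(haps = haps, loci = loci)
}

#' Write phased haplotypes as a VCF file
#'
#' Writes a minimal phased VCF (GT-only FORMAT, `"|"` separators) that
#' round-trips through [read_phased_vcf()]. Haplotype rows are paired into
#' samples in order.
#'
#' @param haps Phased haplotype matrix (2 rows per sample).
#' @param loci Matching locus map.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phased_vcf <- function(haps, loci, path) {
  check_haplotypes(haps, loci)
  n <- nrow(haps) %/% 2L
  samples <- if (is.null(rownames(haps))) sprintf("ind%03d", seq_len(n)) else {
    sub("_h[12]$", "", rownames(haps)[seq(1L, 2L * n, by = 2L)])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  h1 <- haps[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  h2 <- haps[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  for (j in seq_len(nrow(loci))) {
    gts <- paste0(h1[, j], "|", h2[, j])
    writeLines(paste(c(loci$chrom[j], format(loci$pos[j], scientific = FALSE),
                       loci$snp[j], loci$allele_a[j], loci$allele_b[j],
                       ".", "PASS", ".", "GT", gts), collapse = "\t"), con)
  }
  invisible(path)
}
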
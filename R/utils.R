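#' @keywords internal
"_PACKAGE"

## NULL coalescing for defaults
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data frame as a TSV file
#'
#' Plain tab-separated output with a header row, no quoting, no row names —
#' the format used for all pipeline result tables.
#'
#' @param df A data frame.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Order chromosome labels numerically where possible ("1" < "2" < "10"),
## falling back to lexical order for non-numeric labels.
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  ord <- order(is.na(num), num, as.character(chrom))
  rank <- integer(length(chrom))
  rank[ord] <- seq_along(chrom)
  rank
}

## Validate a locus map data frame (chrom, snp, pos at minimum).
check_loci <- function(loci) {
  stopifnot(is.data.frame(loci))
  need <- c("chrom", "snp", "pos")
  miss <- setdiff(need, names(loci))
  if (length(miss) > 0L) {
    stop("locus map is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(loci$snp)) stop("locus map has duplicated SNP names")
  sp <- split(loci$pos, loci$chrom)
  if (any(vapply(sp, is.unsorted, logical(1), strictly = TRUE))) {
    stop("positions must be strictly increasing within each chromosome")
  }
  invisible(loci)
}

## Validate a genotype matrix against a locus map.
check_genotypes <- function(g, loci = NULL) {
  stopifnot(is.matrix(g))
  v <- g[!is.na(g)]
  if (length(v) && !all(v %in% c(0, 1, 2))) {
    stop("genotypes must be coded 0/1/2/NA (copies of allele B)")
  }
  if (!is.null(loci) && ncol(g) != nrow(loci)) {
    stop("genotype matrix has ", ncol(g), " SNPs but locus map has ",
         nrow(loci))
  }
  invisible(g)
}

## Validate a phased haplotype matrix (2 rows per individual, binary, no NA).
check_haplotypes <- function(haps, loci = NULL) {
  stopifnot(is.matrix(haps))
  if (nrow(haps) %% 2L != 0L) {
    stop("haplotype matrix must have an even number of rows (2 per individual)")
  }
  if (anyNA(haps) || !all(haps %in% c(0L, 1L))) {
    stop("haplotypes must be binary 0/1 with no missing values")
  }
  if (!is.null(loci) && ncol(haps) != nrow(loci)) {
    stop("haplotype matrix has ", ncol(haps), " SNPs but locus map has ",
         nrow(loci))
  }
  invisible(haps)
}
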
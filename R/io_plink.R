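#' Read PLINK text PED/MAP genotypes
#'
#' Parses a PLINK text fileset into a 0/1/2/NA genotype matrix coded as
#' copies of allele B, where allele B is the lexically later of the two
#' alleles observed at the locus. The allele pair `0 0` (and half-missing
#' pairs) become `NA`. Loci are sorted by (chromosome, position) and the
#' genotype columns reordered to match.
#'
#' @param ped_path Path to the `.ped` file (>= 6 leading columns, then two
#'   allele columns per SNP).
#' @param map_path Path to the `.map` file (4 columns: chromosome, SNP name,
#'   genetic position, bp position).
#' @return A list with `genotypes` (matrix, row names = individual IDs) and
#'   `loci` (data frame: `chrom`, `snp`, `pos`, `allele_a`, `allele_b`,
#'   `autosomal` — autosomal flagging is left to [qc_filter()]).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(map) != 4L) stop("MAP file must have exactly 4 columns")
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * m
  bad <- which(lengths(fields) != want)
  if (length(bad) > 0L) {
    stop("ragged PED row at line ", bad[1L], ": expected ", want,
         " fields, found ", lengths(fields)[bad[1L]])
  }
  ped <- do.call(rbind, fields)
  ids <- ped[, 2L]
  if (anyDuplicated(ids)) ids <- paste(ped[, 1L], ped[, 2L], sep = "_")

  n <- nrow(ped)
  g <- matrix(NA_integer_, n, m)
  allele_a <- allele_b <- character(m)
  for (j in seq_len(m)) {
    a1 <- ped[, 6L + 2L * j - 1L]
    a2 <- ped[, 6L + 2L * j]
    obs <- sort(setdiff(unique(c(a1, a2)), "0"))
    if (length(obs) > 2L) {
      stop("more than 2 alleles at SNP ", map[j, 2L], ": ",
           paste(obs, collapse = ", "))
    }
    if (length(obs) == 0L) obs <- c("0", "0")
    if (length(obs) == 1L) obs <- c(obs, obs)
    allele_a[j] <- obs[1L]
    allele_b[j] <- obs[2L]
    ok <- a1 != "0" & a2 != "0"
    g[ok, j] <- (a1[ok] == allele_b[j]) + (a2[ok] == allele_b[j])
  }
  rownames(g) <- ids

  loci <- data.frame(chrom = map[, 1L], snp = map[, 2L],
                     pos = as.numeric(map[, 4L]),
                     allele_a = allele_a, allele_b = allele_b,
                     autosomal = NA, stringsAsFactors = FALSE)
  ord <- order(chrom_rank(loci$chrom), loci$pos)
  loci <- loci[ord, , drop = FALSE]
  rownames(loci) <- NULL
  g <- g[, ord, drop = FALSE]
  colnames(g) <- loci$snp
  list(genotypes = g, loci = loci)
}

#' Write PLINK text PED/MAP genotypes
#'
#' Inverse of [read_ped_map()]: genotype 0 is written `allele_a allele_a`,
#' 1 as `allele_a allele_b`, 2 as `allele_b allele_b`, and `NA` as `0 0`.
#'
#' @param g Genotype matrix (0/1/2/NA, individuals x SNPs).
#' @param loci Matching locus map.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, `ped_path`.
#' @export
write_ped_map <- function(g, loci, ped_path, map_path) {
  check_genotypes(g, loci)
  utils::write.table(
    data.frame(loci$chrom, loci$snp, 0, loci$pos),
    map_path, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)

  ids <- rownames(g) %||% sprintf("ind%03d", seq_len(nrow(g)))
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(g))) {
    gi <- g[i, ]
    a1 <- ifelse(is.na(gi), "0", ifelse(gi >= 1, loci$allele_b, loci$allele_a))
    a2 <- ifelse(is.na(gi), "0", ifelse(gi == 2, loci$allele_b, loci$allele_a))
    writeLines(paste(c("FAM1", ids[i], "0", "0", "0", "-9",
                       as.vector(rbind(a1, a2))), collapse = " "), con)
  }
  invisible(ped_path)
}

#' Quality-control filtering of SNP genotypes
#'
#' Applies the standard array QC chain in a fixed order: (1) drop
#' non-autosomal loci; (2) drop samples with call rate below
#' `sample_call_min`; (3) drop SNPs with call rate below `snp_call_min`
#' (computed on the retained samples); (4) drop SNPs with minor allele
#' frequency below `maf_min` (computed on non-missing calls of the retained
#' samples). Defaults match common practice for 50K livestock arrays: MAF >=
#' 0.05 and call rates >= 90%.
#'
#' @param g Genotype matrix (0/1/2/NA).
#' @param loci Matching locus map.
#' @param maf_min Minimum minor allele frequency (SNPs strictly below are
#'   dropped).
#' @param snp_call_min Minimum SNP call rate.
#' @param sample_call_min Minimum per-sample genotyping rate.
#' @param autosomes Character vector of chromosome labels treated as
#'   autosomal (default sheep: `"1"`..`"26"`).
#' @return A list with `genotypes`, `loci` (filtered) and `report`
#'   (class `qc_report`: counts in/out and per-step removals).
#' @export
qc_filter <- function(g, loci, maf_min = 0.05, snp_call_min = 0.90,
                      sample_call_min = 0.90,
                      autosomes = as.character(1:26)) {
  check_genotypes(g, loci)
  n_snps_in <- ncol(g)
  n_samples_in <- nrow(g)

  auto <- loci$chrom %in% autosomes
  removed_nonautosomal <- sum(!auto)
  g <- g[, auto, drop = FALSE]
  loci <- loci[auto, , drop = FALSE]
  loci$autosomal <- TRUE
  if (ncol(g) == 0L) stop("QC removed all SNPs (no autosomal loci)")

  sample_cr <- rowMeans(!is.na(g))
  keep_s <- sample_cr >= sample_call_min
  removed_sample_callrate <- sum(!keep_s)
  g <- g[keep_s, , drop = FALSE]
  if (nrow(g) == 0L) stop("QC removed all samples (call rate filter)")

  snp_cr <- colMeans(!is.na(g))
  keep_cr <- snp_cr >= snp_call_min
  removed_snp_callrate <- sum(!keep_cr)
  g <- g[, keep_cr, drop = FALSE]
  loci <- loci[keep_cr, , drop = FALSE]
  if (ncol(g) == 0L) stop("QC removed all SNPs (call rate filter)")

  maf <- snp_maf(g)
  keep_maf <- !is.na(maf) & maf >= maf_min
  removed_maf <- sum(!keep_maf)
  g <- g[, keep_maf, drop = FALSE]
  loci <- loci[keep_maf, , drop = FALSE]
  if (ncol(g) == 0L) stop("QC removed all SNPs (MAF filter)")
  rownames(loci) <- NULL

  report <- structure(list(
    n_snps_in = n_snps_in, n_snps_out = ncol(g),
    n_samples_in = n_samples_in, n_samples_out = nrow(g),
    removed_nonautosomal = removed_nonautosomal,
    removed_sample_callrate = removed_sample_callrate,
    removed_snp_callrate = removed_snp_callrate,
    removed_maf = removed_maf,
    maf_min = maf_min, snp_call_min = snp_call_min,
    sample_call_min = sample_call_min), class = "qc_report")
  list(genotypes = g, loci = loci, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat(sprintf("  SNPs:    %d in -> %d out (non-autosomal %d, call rate %d, MAF %d)\n",
              x$n_snps_in, x$n_snps_out, x$removed_nonautosomal,
              x$removed_snp_callrate, x$removed_maf))
  cat(sprintf("  samples: %d in -> %d out (call rate %d)\n",
              x$n_samples_in, x$n_samples_out, x$removed_sample_callrate))
  cat(sprintf("  thresholds: MAF >= %.3g, SNP call >= %.3g, sample call >= %.3g\n",
              x$maf_min, x$snp_call_min, x$sample_call_min))
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(metric = names(unclass(x)),
             value = unlist(unclass(x), use.names = FALSE))
}
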
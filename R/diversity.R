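#' Per-SNP minor allele frequency
#'
#' @param g Genotype matrix (0/1/2/NA, copies of allele B).
#' @return Numeric vector of MAF in `[0, 0.5]`; `NA` for SNPs with no
#'   non-missing calls.
#' @export
snp_maf <- function(g) {
  check_genotypes(g)
  n_called <- colSums(!is.na(g))
  p_b <- colSums(g, na.rm = TRUE) / (2 * n_called)
  maf <- pmin(p_b, 1 - p_b)
  maf[n_called == 0L] <- NA_real_
  maf
}

#' Minor allele frequency spectrum
#'
#' Computes per-SNP MAF and bins it into the seven classes conventionally
#' reported for array data: `[0, 0.01]`, then half-open `(0.01, 0.05]`,
#' `(0.05, 0.1]`, `(0.1, 0.2]`, `(0.2, 0.3]`, `(0.3, 0.4]`, `(0.4, 0.5]`.
#' SNPs with undefined MAF (no calls) are excluded from the histogram.
#'
#' @param g Genotype matrix.
#' @return A list with `maf` (per-SNP vector), `class` (factor, `NA` where
#'   MAF is undefined) and `histogram` (named counts over the 7 classes).
#' @export
maf_spectrum <- function(g) {
  maf <- snp_maf(g)
  breaks <- c(0, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)
  cls <- cut(maf, breaks = breaks, include.lowest = TRUE, right = TRUE)
  list(maf = maf, class = cls, histogram = table(cls))
}

#' Proportion of polymorphic SNPs
#'
#' The fraction of SNPs with minor allele frequency strictly above 0.05
#' (P_N), computed over all SNPs supplied.
#'
#' @param maf Numeric vector of per-SNP MAF.
#' @param threshold Polymorphism threshold (default 0.05).
#' @return A proportion in `[0, 1]`.
#' @export
proportion_polymorphic <- function(maf, threshold = 0.05) {
  if (length(maf) == 0L) stop("empty MAF vector")
  sum(maf > threshold, na.rm = TRUE) / length(maf)
}

#' Observed and expected heterozygosity per SNP
#'
#' Per SNP, Ho is the fraction of heterozygous calls among non-missing
#' genotypes and He is the small-sample-corrected expectation
#' `2 p (1 - p) * n / (n - 1)` with `n` the non-missing diploid count — the
#' unbiased estimator PLINK uses, which also makes the expected-homozygosity
#' term of [f_hom()] consistent. SNPs with fewer than 2 calls are excluded
#' with a warning.
#'
#' @param g Genotype matrix.
#' @return A list with `ho`, `he` (per-SNP, `NA` where excluded) and
#'   `summary` (data frame of mean and sample SD of each).
#' @export
ho_he <- function(g) {
  check_genotypes(g)
  if (ncol(g) == 0L) stop("empty genotype matrix")
  n <- colSums(!is.na(g))
  ho <- colSums(g == 1L, na.rm = TRUE) / n
  p <- colSums(g, na.rm = TRUE) / (2 * n)
  he <- 2 * p * (1 - p) * n / (n - 1)
  bad <- n <= 1L
  if (any(bad)) {
    warning(sum(bad), " SNP(s) with <2 genotyped samples excluded from Ho/He")
    ho[bad] <- NA_real_
    he[bad] <- NA_real_
  }
  list(ho = ho, he = he,
       summary = data.frame(
         stat = c("Ho", "He"),
         mean = c(mean(ho, na.rm = TRUE), mean(he, na.rm = TRUE)),
         sd = c(stats::sd(ho[!is.na(ho)]), stats::sd(he[!is.na(he)]))))
}

#' Pairwise identity-by-state sharing and genetic distance
#'
#' For every pair of individuals, counts the loci (complete in both) sharing
#' 0, 1 or 2 alleles identical by state, the allele-sharing coefficient
#' `D_ST = (IBS2 + 0.5 * IBS1) / N`, and the genetic distance `D = 1 - D_ST`.
#' Counting uses indicator-matrix cross-products, so it scales to hundreds of
#' individuals.
#'
#' @param g Genotype matrix (>= 2 individuals).
#' @return A list with `pairs` (data frame: `id1`, `id2`, `ibs0`, `ibs1`,
#'   `ibs2`, `n`, `dst`, `d`) and `summary` (mean and sample SD of `d`).
#' @export
pairwise_distance <- function(g) {
  check_genotypes(g)
  if (nrow(g) < 2L) stop("need at least 2 individuals")
  ids <- rownames(g) %||% sprintf("ind%03d", seq_len(nrow(g)))
  A0 <- (!is.na(g)) & g == 0L; storage.mode(A0) <- "double"; A0[is.na(A0)] <- 0
  A1 <- (!is.na(g)) & g == 1L; storage.mode(A1) <- "double"; A1[is.na(A1)] <- 0
  A2 <- (!is.na(g)) & g == 2L; storage.mode(A2) <- "double"; A2[is.na(A2)] <- 0
  M <- A0 + A1 + A2
  ibs2 <- tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2)
  ibs0 <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  n_mat <- tcrossprod(M)
  ibs1 <- n_mat - ibs2 - ibs0

  up <- which(upper.tri(n_mat), arr.ind = TRUE)
  pairs <- data.frame(id1 = ids[up[, 1L]], id2 = ids[up[, 2L]],
                      ibs0 = ibs0[up], ibs1 = ibs1[up], ibs2 = ibs2[up],
                      n = n_mat[up], stringsAsFactors = FALSE)
  empty <- pairs$n == 0
  if (any(empty)) {
    warning(sum(empty), " pair(s) with no loci complete in both skipped")
    pairs <- pairs[!empty, , drop = FALSE]
  }
  pairs$dst <- (pairs$ibs2 + 0.5 * pairs$ibs1) / pairs$n
  pairs$d <- 1 - pairs$dst
  list(pairs = pairs,
       summary = data.frame(stat = "D", mean = mean(pairs$d),
                            sd = stats::sd(pairs$d)))
}

#' Method-of-moments inbreeding coefficient F_HOM
#'
#' Per individual, `F_HOM = (O - E) / (L - E)` where `O` is the observed
#' number of homozygous loci among the individual's `L` non-missing loci and
#' `E` is the expected homozygous count under Hardy–Weinberg at cohort allele
#' frequencies, `E = sum(1 - 2 p (1-p) * n/(n-1))` over those loci (the
#' same small-sample correction as [ho_he()], matching PLINK `--het`).
#' Individuals with `L = E` (all loci uninformative) get `NA`.
#'
#' @param g Genotype matrix.
#' @return Named numeric vector of per-individual F_HOM.
#' @export
f_hom <- function(g) {
  check_genotypes(g)
  n <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * n)
  e_hom <- 1 - 2 * p * (1 - p) * n / pmax(n - 1, 1)
  e_hom[n <= 1L] <- NA_real_

  res <- vapply(seq_len(nrow(g)), function(i) {
    ok <- !is.na(g[i, ]) & !is.na(e_hom)
    L <- sum(ok)
    if (L == 0L) return(NA_real_)
    O <- sum(g[i, ok] != 1L)
    E <- sum(e_hom[ok])
    if (abs(L - E) < 1e-12) return(NA_real_)
    (O - E) / (L - E)
  }, numeric(1))
  names(res) <- rownames(g) %||% sprintf("ind%03d", seq_len(nrow(g)))
  res
}

#' One-row genetic-diversity and inbreeding summary
#'
#' Assembles the population summary conventionally reported for a diversity
#' panel: mean +/- SD of MAF, the proportion of polymorphic SNPs, mean +/- SD
#' of Ho, He and pairwise D, and the cohort means of F_ROH and F_HOM (the
#' latter two optional, passed in from the ROH stage).
#'
#' @param g Genotype matrix (post-QC).
#' @param froh Optional per-individual F_ROH vector (see [f_roh()]).
#' @return A one-row data frame.
#' @export
diversity_summary <- function(g, froh = NULL) {
  sp <- maf_spectrum(g)
  hh <- ho_he(g)
  pd <- pairwise_distance(g)
  fh <- f_hom(g)
  data.frame(
    maf_mean = mean(sp$maf, na.rm = TRUE),
    maf_sd = stats::sd(sp$maf[!is.na(sp$maf)]),
    p_n = proportion_polymorphic(sp$maf),
    ho_mean = hh$summary$mean[1L], ho_sd = hh$summary$sd[1L],
    he_mean = hh$summary$mean[2L], he_sd = hh$summary$sd[2L],
    d_mean = pd$summary$mean, d_sd = pd$summary$sd,
    froh_mean = if (is.null(froh)) NA_real_ else mean(froh, na.rm = TRUE),
    froh_sd = if (is.null(froh)) NA_real_ else stats::sd(froh[!is.na(froh)]),
    fhom_mean = mean(fh, na.rm = TRUE),
    fhom_sd = stats::sd(fh[!is.na(fh)]))
}
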
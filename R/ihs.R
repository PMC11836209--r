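#' Ancestral-allele assignment
#'
#' Without outgroup information the ancestral state at each SNP must be
#' assigned by convention. Two strategies are supported: `"major"` takes the
#' higher-frequency allele as ancestral (ties at frequency 0.5 resolve to
#' allele 0, deterministically), and `"random"` draws the ancestral state by
#' a fair coin per SNP from `seed`. Monomorphic SNPs have no derived allele
#' and are marked unanalyzable (`NA`).
#'
#' @param haps Phased haplotype matrix.
#' @param mode `"major"` or `"random"`.
#' @param seed Integer seed (required for `"random"`).
#' @return Integer vector per SNP: ancestral allele 0/1, `NA` where
#'   monomorphic.
#' @export
assign_ancestral <- function(haps, mode = c("major", "random"), seed = NULL) {
  check_haplotypes(haps)
  mode <- match.arg(mode)
  freq1 <- colMeans(haps)
  anc <- if (mode == "major") {
    ifelse(freq1 > 0.5, 1L, 0L)
  } else {
    if (is.null(seed)) stop("random mode requires a seed")
    set.seed(seed)
    stats::rbinom(ncol(haps), 1L, 0.5)
  }
  anc[freq1 == 0 | freq1 == 1] <- NA_integer_
  as.integer(anc)
}

## EHH at one flanking step for carrier group ids: sum over groups of
## C(k_g,2) / C(n,2).
.ehh_value <- function(gid, n) {
  cnt <- tabulate(gid)
  sum(cnt * (cnt - 1)) / (n * (n - 1))
}

## Walk one side of the EHH curve. Returns positions, EHH values (focal
## excluded), whether the side hit the chromosome end with EHH >= cutoff,
## and the last EHH value.
.ehh_side <- function(H, pos, carriers, j, dir, cutoff) {
  k <- length(carriers)
  gid <- rep.int(1L, k)
  m <- length(pos)
  x <- j + dir
  p_out <- numeric(0)
  e_out <- numeric(0)
  while (x >= 1L && x <= m) {
    a <- H[carriers, x]
    key <- gid * 2L + a
    gid <- match(key, unique.default(key))
    e <- .ehh_value(gid, k)
    p_out <- c(p_out, pos[x])
    e_out <- c(e_out, e)
    if (e < cutoff) {
      return(list(pos = p_out, ehh = e_out, truncated = FALSE))
    }
    x <- x + dir
  }
  list(pos = p_out, ehh = e_out, truncated = TRUE)
}

#' Extended haplotype homozygosity curve for one allele
#'
#' EHH at a flanking SNP x is the probability that two haplotypes drawn
#' without replacement from the carriers of `allele` at the focal SNP are
#' identical at every SNP from the focal out to x: distinct haplotype strings
#' are grouped and `EHH = sum C(k_g, 2) / C(n_a, 2)`. The curve starts at 1
#' at the focal SNP and is computed outward on each side until it drops below
#' `cutoff` (that boundary point is kept) or the chromosome ends (the side is
#' flagged truncated).
#'
#' @param haps Phased haplotype matrix.
#' @param loci Matching locus map.
#' @param focal_snp SNP name or column index of the focal SNP.
#' @param allele Focal allele, 0 or 1.
#' @param cutoff EHH value below which the curve is no longer followed.
#' @return A list of class `ehh_curve`: `snp`, `allele`, `n_carriers`,
#'   `curve` (data frame `pos`, `ehh`, ordered by position, focal included),
#'   `truncated_left`, `truncated_right`.
#' @export
ehh <- function(haps, loci, focal_snp, allele, cutoff = 0.05) {
  check_haplotypes(haps, loci)
  j <- if (is.character(focal_snp)) match(focal_snp, loci$snp) else focal_snp
  if (is.na(j) || j < 1L || j > ncol(haps)) stop("focal SNP not found")
  stopifnot(allele %in% c(0L, 1L))
  cols <- which(loci$chrom == loci$chrom[j])
  jj <- match(j, cols)
  H <- haps[, cols, drop = FALSE]
  pos <- loci$pos[cols]
  carriers <- which(H[, jj] == allele)
  if (length(carriers) < 2L) {
    stop("fewer than 2 carriers of allele ", allele, " at ", loci$snp[j])
  }
  left <- .ehh_side(H, pos, carriers, jj, -1L, cutoff)
  right <- .ehh_side(H, pos, carriers, jj, 1L, cutoff)
  curve <- data.frame(
    pos = c(rev(left$pos), pos[jj], right$pos),
    ehh = c(rev(left$ehh), 1, right$ehh))
  structure(list(snp = loci$snp[j], allele = as.integer(allele),
                 n_carriers = length(carriers), curve = curve,
                 focal_pos = pos[jj],
                 truncated_left = left$truncated,
                 truncated_right = right$truncated),
            class = "ehh_curve")
}

#' Integrated EHH (trapezoid area under the curve)
#'
#' Integrates an EHH curve over physical distance by the trapezoid rule,
#' both sides of the focal SNP summed. The point at which EHH first fell
#' below the cutoff is included as the curve boundary.
#'
#' @param curve An `ehh_curve` from [ehh()].
#' @return Area in bp x EHH units.
#' @export
ihh <- function(curve) {
  stopifnot(inherits(curve, "ehh_curve"))
  p <- curve$curve$pos
  e <- curve$curve$ehh
  if (length(p) < 2L) return(0)
  sum(0.5 * (e[-1L] + e[-length(e)]) * diff(p))
}

## Area of one side from .ehh_side output (focal at pos0 with EHH 1).
.side_area <- function(side, pos0) {
  p <- c(pos0, side$pos)
  e <- c(1, side$ehh)
  if (length(p) < 2L) return(0)
  sum(0.5 * (e[-1L] + e[-length(e)]) * abs(diff(p)))
}

#' Integrated EHH for both alleles at every analyzable SNP
#'
#' The expensive half of the iHS scan, independent of the ancestral
#' assignment: for each SNP with minor allele frequency at least `maf_min`,
#' computes the integrated EHH of allele 0 and allele 1 separately. A SNP is
#' flagged unreliable (`ok = FALSE`) when either allele's curve reaches a
#' chromosome end while EHH is still above `border_cutoff`, when an allele
#' has fewer than 2 carriers, or when either area is zero — such SNPs are
#' excluded from standardization downstream.
#'
#' @param haps Phased haplotype matrix.
#' @param loci Matching locus map.
#' @param ehh_cutoff Stop following an EHH curve below this value.
#' @param border_cutoff Chromosome-end truncation with EHH above this value
#'   marks the SNP unreliable.
#' @param maf_min SNPs below this minor allele frequency are never scored.
#' @return Data frame per SNP: `snp`, `chrom`, `pos`, `freq1`, `ihh0`,
#'   `ihh1`, `ok`.
#' @export
ihh_scan <- function(haps, loci, ehh_cutoff = 0.05, border_cutoff = 0.10,
                     maf_min = 0.05) {
  check_haplotypes(haps, loci)
  check_loci(loci)
  freq1 <- colMeans(haps)
  maf <- pmin(freq1, 1 - freq1)
  out <- data.frame(snp = loci$snp, chrom = loci$chrom, pos = loci$pos,
                    freq1 = freq1, ihh0 = NA_real_, ihh1 = NA_real_,
                    ok = FALSE, stringsAsFactors = FALSE)
  for (ch in unique(loci$chrom)) {
    cols <- which(loci$chrom == ch)
    H <- haps[, cols, drop = FALSE]
    pos <- loci$pos[cols]
    for (jj in seq_along(cols)) {
      j <- cols[jj]
      if (maf[j] < maf_min) next
      areas <- numeric(2L)
      reliable <- TRUE
      for (al in c(0L, 1L)) {
        carriers <- which(H[, jj] == al)
        if (length(carriers) < 2L) { reliable <- FALSE; break }
        left <- .ehh_side(H, pos, carriers, jj, -1L, ehh_cutoff)
        right <- .ehh_side(H, pos, carriers, jj, 1L, ehh_cutoff)
        end_ehh_l <- if (length(left$ehh)) left$ehh[length(left$ehh)] else 1
        end_ehh_r <- if (length(right$ehh)) right$ehh[length(right$ehh)] else 1
        if ((left$truncated && end_ehh_l > border_cutoff) ||
            (right$truncated && end_ehh_r > border_cutoff)) {
          reliable <- FALSE
        }
        areas[al + 1L] <- .side_area(left, pos[jj]) +
          .side_area(right, pos[jj])
      }
      out$ihh0[j] <- areas[1L]
      out$ihh1[j] <- areas[2L]
      out$ok[j] <- reliable && all(areas > 0)
    }
  }
  out
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Centers and scales the unstandardized `ln(iHH_A / iHH_D)` within bins of
#' derived allele frequency (width `bin_width`), using the sample SD, so
#' that the score is comparable across frequencies. Bins holding fewer than
#' `min_bin` SNPs are merged with their right neighbour (the last bin merges
#' left) until all bins are large enough.
#'
#' @param u Unstandardized values.
#' @param derived_freq Derived allele frequency per value.
#' @param bin_width Frequency bin width (default 0.05).
#' @param min_bin Minimum SNPs per bin before merging.
#' @return A list with `z` (standardized values) and `bin` (final bin index
#'   per value).
#' @export
standardize_ihs <- function(u, derived_freq, bin_width = 0.05,
                            min_bin = 10L) {
  stopifnot(length(u) == length(derived_freq))
  edges <- seq(0, 1, by = bin_width)
  if (edges[length(edges)] < 1) edges <- c(edges, 1)
  bin <- findInterval(derived_freq, edges, rightmost.closed = TRUE)
  ## merge sparse bins into their right neighbour (last bin merges left)
  repeat {
    present <- sort(unique(bin))
    sizes <- table(factor(bin, levels = present))
    small <- present[sizes < min_bin]
    if (length(small) == 0L || length(present) == 1L) break
    b <- small[1L]
    pos_b <- match(b, present)
    target <- if (pos_b < length(present)) present[pos_b + 1L] else
      present[pos_b - 1L]
    bin[bin == b] <- target
  }
  if (length(unique(bin)) == 1L && stats::sd(u) == 0) {
    stop("cannot standardize: a single bin with zero variance")
  }
  z <- rep(NA_real_, length(u))
  for (b in unique(bin)) {
    in_b <- bin == b
    s <- stats::sd(u[in_b])
    if (is.na(s) || s == 0) {
      stop("cannot standardize: bin with zero variance")
    }
    z[in_b] <- (u[in_b] - mean(u[in_b])) / s
  }
  list(z = z, bin = bin)
}

#' Integrated haplotype score scan
#'
#' Computes the standardized iHS per SNP: `ln(iHH_A / iHH_D)` from the
#' per-allele integrated EHH areas, standardized within derived-allele-
#' frequency bins, with the extreme flag set where `|iHS|` strictly exceeds
#' `extreme_threshold`. SNPs that are monomorphic, below `maf_min`, or
#' flagged unreliable by [ihh_scan()] get `NA`.
#'
#' @param haps Phased haplotype matrix.
#' @param loci Matching locus map.
#' @param mode Ancestral-assignment mode, see [assign_ancestral()].
#' @param seed Seed for `"random"` mode.
#' @param scan Optional precomputed [ihh_scan()] table (reused across
#'   assignment replicates).
#' @param bin_width,min_bin Standardization bins, see [standardize_ihs()].
#' @param extreme_threshold Extreme-SNP cutoff on `|iHS|` (default 3.2).
#' @param ... Passed to [ihh_scan()] when `scan` is not supplied.
#' @return Data frame per SNP: `snp`, `chrom`, `pos`, `ancestral`,
#'   `derived_freq`, `ihh_a`, `ihh_d`, `uihs`, `ihs`, `abs_ihs`, `extreme`.
#' @export
ihs_scan <- function(haps, loci, mode = c("major", "random"), seed = NULL,
                     scan = NULL, bin_width = 0.05, min_bin = 10L,
                     extreme_threshold = 3.2, ...) {
  mode <- match.arg(mode)
  if (is.null(scan)) scan <- ihh_scan(haps, loci, ...)
  anc <- assign_ancestral(haps, mode, seed)
  ihs_from_scan(scan, anc, bin_width = bin_width, min_bin = min_bin,
                extreme_threshold = extreme_threshold)
}

#' Turn a per-allele iHH table plus an ancestral assignment into iHS
#'
#' @param scan An [ihh_scan()] table.
#' @param ancestral Integer vector (0/1/NA) of ancestral alleles per SNP.
#' @param bin_width,min_bin,extreme_threshold See [ihs_scan()].
#' @return Same shape as [ihs_scan()].
#' @export
ihs_from_scan <- function(scan, ancestral, bin_width = 0.05, min_bin = 10L,
                          extreme_threshold = 3.2) {
  stopifnot(length(ancestral) == nrow(scan))
  ihh_a <- ifelse(ancestral == 1L, scan$ihh1, scan$ihh0)
  ihh_d <- ifelse(ancestral == 1L, scan$ihh0, scan$ihh1)
  derived_freq <- ifelse(ancestral == 1L, 1 - scan$freq1, scan$freq1)
  usable <- scan$ok & !is.na(ancestral)
  uihs <- rep(NA_real_, nrow(scan))
  uihs[usable] <- log(ihh_a[usable] / ihh_d[usable])
  out <- data.frame(snp = scan$snp, chrom = scan$chrom, pos = scan$pos,
                    ancestral = ancestral, derived_freq = derived_freq,
                    ihh_a = ihh_a, ihh_d = ihh_d, uihs = uihs,
                    ihs = NA_real_, stringsAsFactors = FALSE)
  if (any(usable)) {
    st <- standardize_ihs(uihs[usable], derived_freq[usable],
                          bin_width = bin_width, min_bin = min_bin)
    out$ihs[usable] <- st$z
  }
  out$abs_ihs <- abs(out$ihs)
  out$extreme <- call_extreme(out$ihs, extreme_threshold)
  out
}

#' Flag extreme iHS values
#'
#' Strict inequality: `|iHS| > threshold`.
#'
#' @param ihs Standardized iHS values (vector or a scan data frame with an
#'   `ihs` column).
#' @param threshold Extreme cutoff (default 3.2).
#' @return Logical vector (`FALSE` for `NA` scores), or the data frame with
#'   its `extreme` column replaced.
#' @export
call_extreme <- function(ihs, threshold = 3.2) {
  if (is.data.frame(ihs)) {
    ihs$extreme <- call_extreme(ihs$ihs, threshold)
    return(ihs)
  }
  !is.na(ihs) & abs(ihs) > threshold
}

#' Random-assignment iHS replicates
#'
#' Repeats the iHS computation under `n_reps` independent random ancestral
#' assignments (the integrated EHH areas are assignment-invariant, so they
#' are computed once and each replicate only re-labels alleles and
#' re-standardizes). Reports the per-SNP mean and SD of `|iHS|` across
#' replicates, and a Spearman rank-correlation diagnostic of the mean
#' against the major-allele mode so agreement between the two assignment
#' strategies can be checked.
#'
#' @param haps Phased haplotype matrix.
#' @param loci Matching locus map.
#' @param n_reps Number of random assignments (the conventional choice is
#'   100).
#' @param seed Integer seed; replicate seeds are drawn from it.
#' @param scan Optional precomputed [ihh_scan()] table.
#' @param extreme_threshold Extreme cutoff applied to the per-SNP mean
#'   `|iHS|`, so the aggregate feeds [call_ihs_regions()] directly.
#' @param ... Passed to [ihs_scan()] / [ihh_scan()].
#' @return A list with `per_snp` (data frame: `snp`, `chrom`, `pos`,
#'   `mean_abs_ihs`, `sd_abs_ihs`, `n_scored`, plus `ihs`/`abs_ihs`/`extreme`
#'   columns carrying the mean `|iHS|` aggregate), `major` (the major-allele
#'   scan), and `rank_cor` (Spearman correlation of mean `|iHS|` vs the
#'   major-mode `|iHS|`).
#' @export
run_random_replicates <- function(haps, loci, n_reps = 100L, seed = 1,
                                  scan = NULL, extreme_threshold = 3.2,
                                  ...) {
  if (is.null(scan)) scan <- ihh_scan(haps, loci, ...)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  acc <- matrix(NA_real_, nrow(scan), n_reps)
  for (r in seq_len(n_reps)) {
    res <- ihs_scan(haps, loci, mode = "random", seed = rep_seeds[r],
                    scan = scan)
    acc[, r] <- res$abs_ihs
  }
  major <- ihs_scan(haps, loci, mode = "major", scan = scan,
                    extreme_threshold = extreme_threshold)
  per_snp <- data.frame(
    snp = scan$snp, chrom = scan$chrom, pos = scan$pos,
    mean_abs_ihs = rowMeans(acc, na.rm = TRUE),
    sd_abs_ihs = apply(acc, 1L, function(v) stats::sd(v[!is.na(v)])),
    n_scored = rowSums(!is.na(acc)), stringsAsFactors = FALSE)
  per_snp$mean_abs_ihs[per_snp$n_scored == 0L] <- NA_real_
  per_snp$ihs <- per_snp$mean_abs_ihs
  per_snp$abs_ihs <- per_snp$mean_abs_ihs
  per_snp$extreme <- call_extreme(per_snp$mean_abs_ihs, extreme_threshold)
  ok <- !is.na(per_snp$mean_abs_ihs) & !is.na(major$abs_ihs)
  rank_cor <- if (sum(ok) >= 3L) {
    stats::cor(per_snp$mean_abs_ihs[ok], major$abs_ihs[ok],
               method = "spearman")
  } else NA_real_
  list(per_snp = per_snp, major = major, rank_cor = rank_cor,
       n_reps = n_reps)
}
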
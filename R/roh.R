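#' Minimum SNP count for ROH detection (false-positive bound)
#'
#' The minimum number of homozygous SNPs a window (and a run) must contain so
#' that the expected number of chance runs across the dataset stays below the
#' false-positive budget `a`:
#' `L = ln(a / (n_s * n_i)) / ln(1 - het)`, rounded up. Rounding up (rather
#' than to the nearest integer) guarantees the bound.
#'
#' @param a Acceptable false-positive rate, in (0, 1).
#' @param n_s Number of genotyped SNPs per individual.
#' @param n_i Number of genotyped individuals.
#' @param het Mean heterozygosity, in (0, 1).
#' @param raw If `TRUE`, return the unrounded value.
#' @return Integer SNP threshold (or the raw numeric value).
#' @export
min_snp_threshold <- function(a, n_s, n_i, het, raw = FALSE) {
  if (a <= 0 || a >= 1) stop("a must be in (0, 1)")
  if (n_s < 1 || n_i < 1) stop("n_s and n_i must be >= 1")
  if (het <= 0 || het >= 1) stop("het must be in (0, 1)")
  L <- log(a / (n_s * n_i)) / log(1 - het)
  if (raw) L else as.integer(ceiling(L))
}

#' ROH detection parameters
#'
#' Sliding-window parameters for runs-of-homozygosity detection. Defaults
#' follow standard practice for 50K livestock arrays: at most 1 heterozygote
#' and 2 missing calls per window, a 1 Mb cap on the gap between consecutive
#' SNPs inside a run, a 1 Mb minimum run length, a density of at least 1 SNP
#' per 100 kb, and a per-SNP window-hit proportion threshold of 0.05.
#' `min_snps` (window size and minimum SNPs per run) has no universal
#' default; compute it from the data with [min_snp_threshold()].
#'
#' @param min_snps Window size = minimum SNPs per run.
#' @param max_het Maximum heterozygous calls per window.
#' @param max_missing Maximum missing calls per window.
#' @param max_gap Maximum gap (bp) between consecutive SNPs inside a run.
#' @param min_length Minimum run length in bp.
#' @param max_bp_per_snp Density ceiling: a run must have at least one SNP
#'   per this many bp.
#' @param hit_threshold A SNP is a run candidate when the proportion of
#'   homozygous windows covering it exceeds this value (strictly).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_snps, max_het = 1L, max_missing = 2L,
                       max_gap = 1e6, min_length = 1e6,
                       max_bp_per_snp = 1e5, hit_threshold = 0.05) {
  stopifnot(min_snps >= 1, max_het >= 0, max_missing >= 0, max_gap > 0,
            min_length > 0, max_bp_per_snp > 0,
            hit_threshold >= 0, hit_threshold < 1)
  structure(list(min_snps = as.integer(min_snps),
                 max_het = as.integer(max_het),
                 max_missing = as.integer(max_missing),
                 max_gap = as.numeric(max_gap),
                 min_length = as.numeric(min_length),
                 max_bp_per_snp = as.numeric(max_bp_per_snp),
                 hit_threshold = as.numeric(hit_threshold)),
            class = "roh_params")
}

## Segment one individual's candidate vector on one chromosome into runs.
## cand: logical per SNP; pos: positions; returns start/end indices.
.runs_from_candidates <- function(cand, pos, params) {
  r <- rle(cand)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    ## split stretches at gaps exceeding max_gap
    cut_at <- if (i1 > i0) which(diff(pos[i0:i1]) > params$max_gap) else integer()
    seg_start <- c(i0, i0 + cut_at)
    seg_end <- c(i0 + cut_at - 1L, i1)
    for (s in seq_along(seg_start)) {
      a <- seg_start[s]; b <- seg_end[s]
      n_snps <- b - a + 1L
      len <- pos[b] - pos[a] + 1
      if (n_snps >= params$min_snps && len >= params$min_length &&
          len <= n_snps * params$max_bp_per_snp) {
        out[[length(out) + 1L]] <- c(a, b)
      }
    }
  }
  out
}

## Candidate status of every SNP for one genotype vector on one chromosome:
## slide a window of min_snps SNPs; a window is a hit if it holds <= max_het
## heterozygotes and <= max_missing missing calls; a SNP is a candidate if
## hits covering it / windows covering it > hit_threshold.
.roh_candidates <- function(gi, params) {
  m <- length(gi)
  w <- params$min_snps
  if (m < w) return(NULL)
  het <- as.numeric(!is.na(gi) & gi == 1L)
  mis <- as.numeric(is.na(gi))
  ch <- cumsum(het); cm <- cumsum(mis)
  ws <- seq_len(m - w + 1L)
  het_w <- ch[ws + w - 1L] - c(0, ch)[ws]
  mis_w <- cm[ws + w - 1L] - c(0, cm)[ws]
  hit <- as.numeric(het_w <= params$max_het & mis_w <= params$max_missing)
  chit <- c(0, cumsum(hit))
  lo <- pmax(1L, seq_len(m) - w + 1L)
  hi <- pmin(seq_len(m), m - w + 1L)
  n_cover <- hi - lo + 1L
  n_hit <- chit[hi + 1L] - chit[lo]
  n_hit / n_cover > params$hit_threshold
}

#' Detect runs of homozygosity by sliding window
#'
#' For each individual and chromosome, slides a window of `min_snps` SNPs one
#' SNP at a time; windows with at most `max_het` heterozygous and
#' `max_missing` missing calls are "hits". Each SNP's hit proportion is the
#' fraction of windows covering it that are hits; SNPs whose proportion
#' exceeds `hit_threshold` are run candidates. Maximal candidate stretches
#' are split wherever consecutive SNPs are more than `max_gap` apart, then
#' kept as runs only if they satisfy the SNP-count, length and density
#' constraints. Run coordinates are the first and last SNP positions (1-based
#' closed); length is `end - start + 1`.
#'
#' @param g Genotype matrix (0/1/2/NA).
#' @param loci Matching locus map, sorted by (chromosome, position).
#' @param params A [roh_params()].
#' @return Data frame of segments: `individual`, `chrom`, `start`, `end`,
#'   `n_snps`, `length`.
#' @export
detect_roh <- function(g, loci, params) {
  check_genotypes(g, loci)
  check_loci(loci)
  stopifnot(inherits(params, "roh_params"))
  ids <- rownames(g) %||% sprintf("ind%03d", seq_len(nrow(g)))
  chroms <- unique(loci$chrom)
  segs <- list()
  warned <- character()
  for (ch in chroms) {
    cols <- which(loci$chrom == ch)
    if (length(cols) < params$min_snps) {
      warned <- c(warned, ch)
      next
    }
    pos <- loci$pos[cols]
    for (i in seq_len(nrow(g))) {
      cand <- .roh_candidates(g[i, cols], params)
      if (is.null(cand) || !any(cand)) next
      for (ab in .runs_from_candidates(cand, pos, params)) {
        segs[[length(segs) + 1L]] <- data.frame(
          individual = ids[i], chrom = ch,
          start = pos[ab[1L]], end = pos[ab[2L]],
          n_snps = ab[2L] - ab[1L] + 1L,
          length = pos[ab[2L]] - pos[ab[1L]] + 1,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(warned) > 0L) {
    warning("chromosome(s) with fewer SNPs than the window skipped: ",
            paste(warned, collapse = ", "))
  }
  if (length(segs) == 0L) {
    return(data.frame(individual = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_snps = integer(), length = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Classify ROH segments by length
#'
#' Bins segments into the five classes conventionally reported for livestock
#' (`[1,5)`, `[5,10)`, `[10,20)`, `[20,40)`, `[40,Inf)` Mb) and reports per
#' class: count, percentage of all runs, mean length, and the mean and SD
#' over individuals of the per-individual F_ROH contribution of that class.
#'
#' @param segments Segment table from [detect_roh()].
#' @param loci Locus map (for the SNP-covered genome length).
#' @param individuals Vector of all individual labels (so animals without
#'   runs contribute zeros to the F_ROH columns).
#' @return Data frame with one row per class.
#' @export
classify_roh <- function(segments, loci, individuals) {
  breaks <- c(1, 5, 10, 20, 40, Inf)
  labels <- c("1-5", "5-10", "10-20", "20-40", ">40")
  lg <- genome_length(loci)
  len_mb <- segments$length / 1e6
  cls <- cut(len_mb, breaks = breaks, right = FALSE, labels = labels)
  out <- data.frame(class_mb = labels, n = 0L, percent = 0,
                    mean_length_mb = NA_real_,
                    froh_mean = 0, froh_sd = 0, stringsAsFactors = FALSE)
  total <- nrow(segments)
  for (k in seq_along(labels)) {
    in_k <- !is.na(cls) & cls == labels[k]
    out$n[k] <- sum(in_k)
    out$percent[k] <- if (total > 0) 100 * sum(in_k) / total else 0
    out$mean_length_mb[k] <- if (any(in_k)) mean(len_mb[in_k]) else NA_real_
    contrib <- stats::setNames(rep(0, length(individuals)), individuals)
    if (any(in_k)) {
      s <- tapply(segments$length[in_k], segments$individual[in_k], sum)
      contrib[names(s)] <- s / lg
    }
    out$froh_mean[k] <- mean(contrib)
    out$froh_sd[k] <- stats::sd(contrib)
  }
  out
}

#' SNP-covered genome length
#'
#' Sum over chromosomes of (last SNP position - first SNP position), the
#' denominator of F_ROH.
#'
#' @param loci Locus map.
#' @return Length in bp.
#' @export
genome_length <- function(loci) {
  lg <- sum(tapply(loci$pos, loci$chrom, function(p) max(p) - min(p)))
  if (lg <= 0) stop("SNP-covered genome length is zero")
  lg
}

#' ROH-based inbreeding coefficient F_ROH
#'
#' Per individual, the summed length of its runs of homozygosity divided by
#' the SNP-covered genome length; individuals with no runs get 0.
#'
#' @param segments Segment table from [detect_roh()].
#' @param loci Locus map.
#' @param individuals Vector of all individual labels.
#' @return Named numeric vector of F_ROH in `[0, 1]`.
#' @export
f_roh <- function(segments, loci, individuals) {
  lg <- genome_length(loci)
  out <- stats::setNames(rep(0, length(individuals)), individuals)
  if (nrow(segments) > 0L) {
    s <- tapply(segments$length, segments$individual, sum)
    out[names(s)] <- s / lg
  }
  out
}

#' Pearson correlation between two inbreeding coefficients
#'
#' @param froh,fhom Equal-length per-individual coefficient vectors
#'   (>= 3 complete pairs).
#' @return Pearson r, or `NA` (with a warning) if either vector has zero
#'   variance.
#' @export
correlate_inbreeding <- function(froh, fhom) {
  if (length(froh) != length(fhom)) stop("vectors must have equal length")
  ok <- !is.na(froh) & !is.na(fhom)
  if (sum(ok) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(froh[ok]) == 0 || stats::sd(fhom[ok]) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(froh[ok], fhom[ok])
}

#' Per-SNP ROH incidence
#'
#' For every SNP, the proportion of individuals whose runs of homozygosity
#' cover its position — the quantity plotted in ROH Manhattan graphs and
#' thresholded to call ROH islands.
#'
#' @param segments Segment table from [detect_roh()].
#' @param loci Locus map.
#' @param n_individuals Number of individuals in the cohort.
#' @return Numeric vector (aligned to `loci`) of proportions in `[0, 1]`.
#' @export
snp_roh_incidence <- function(segments, loci, n_individuals) {
  counts <- numeric(nrow(loci))
  for (k in seq_len(nrow(segments))) {
    covered <- loci$chrom == segments$chrom[k] &
      loci$pos >= segments$start[k] & loci$pos <= segments$end[k]
    counts[covered] <- counts[covered] + 1
  }
  counts / n_individuals
}

#' Call ROH islands (shared-run selection signatures)
#'
#' Maximal stretches of consecutive SNPs whose ROH incidence is at least
#' `threshold` (inclusive — "at least 10% of the animals" by default) are
#' reported as candidate sweep regions.
#'
#' @param incidence Per-SNP incidence from [snp_roh_incidence()].
#' @param loci Locus map aligned with `incidence`.
#' @param threshold Inclusive incidence threshold (default 0.10).
#' @return Data frame of regions: `method` (`"ROH"`), `chrom`, `start`,
#'   `end`, `start_snp`, `end_snp`, `n_snps`, `peak_snp`, `peak_value`.
#' @export
roh_islands <- function(incidence, loci, threshold = 0.10) {
  stopifnot(length(incidence) == nrow(loci))
  out <- list()
  for (ch in unique(loci$chrom)) {
    cols <- which(loci$chrom == ch)
    cand <- incidence[cols] >= threshold
    if (!any(cand)) next
    r <- rle(cand)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- cols[starts[k]:ends[k]]
      peak <- idx[which.max(incidence[idx])]
      out[[length(out) + 1L]] <- data.frame(
        method = "ROH", chrom = ch,
        start = loci$pos[idx[1L]], end = loci$pos[idx[length(idx)]],
        start_snp = loci$snp[idx[1L]], end_snp = loci$snp[idx[length(idx)]],
        n_snps = length(idx), peak_snp = loci$snp[peak],
        peak_value = incidence[peak], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(method = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      start_snp = character(), end_snp = character(),
                      n_snps = integer(), peak_snp = character(),
                      peak_value = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
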
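# Independent brute-force oracles. Deliberately naive: they re-derive the
# same quantities as the package from first principles, without sharing any
# of the implementation's incremental machinery.

# EHH by direct pairwise comparison: among carriers of `allele` at focal SNP
# j (chromosome-local matrix H, positions pos), the EHH at flanking SNP x is
# the fraction of carrier pairs identical at every SNP between j and x.
# Returns the same curve shape as ehh(): walked outward per side until the
# value drops below `cutoff` (kept) or the chromosome ends.
ehh_pairwise_oracle <- function(H, pos, j, allele, cutoff = 0.05) {
  carriers <- which(H[, j] == allele)
  k <- length(carriers)
  stopifnot(k >= 2)
  pairs <- utils::combn(carriers, 2)
  ehh_at <- function(x) {
    lo <- min(j, x); hi <- max(j, x)
    same <- vapply(seq_len(ncol(pairs)), function(q) {
      all(H[pairs[1, q], lo:hi] == H[pairs[2, q], lo:hi])
    }, logical(1))
    sum(same) / ncol(pairs)
  }
  walk <- function(dir) {
    p <- numeric(0); e <- numeric(0); x <- j + dir
    while (x >= 1 && x <= ncol(H)) {
      v <- ehh_at(x)
      p <- c(p, pos[x]); e <- c(e, v)
      if (v < cutoff) return(list(pos = p, ehh = e, truncated = FALSE))
      x <- x + dir
    }
    list(pos = p, ehh = e, truncated = TRUE)
  }
  left <- walk(-1L); right <- walk(1L)
  data.frame(pos = c(rev(left$pos), pos[j], right$pos),
             ehh = c(rev(left$ehh), 1, right$ehh))
}

# ROH by exhaustive interval enumeration for one individual on one
# chromosome. Candidate status is recomputed with naive per-window loops;
# runs are all maximal intervals of candidate SNPs with no internal gap
# above max_gap, filtered by the SNP-count/length/density rules.
roh_exhaustive_oracle <- function(gi, pos, params) {
  m <- length(gi)
  w <- params$min_snps
  if (m < w) return(NULL)
  hit <- logical(m - w + 1)
  for (s in seq_len(m - w + 1)) {
    win <- gi[s:(s + w - 1)]
    hit[s] <- sum(win == 1, na.rm = TRUE) <= params$max_het &&
      sum(is.na(win)) <= params$max_missing
  }
  cand <- logical(m)
  for (j in seq_len(m)) {
    covering <- intersect(seq_len(m - w + 1), (j - w + 1):j)
    cand[j] <- mean(hit[covering]) > params$hit_threshold
  }
  # boundaries: candidate-status change or an over-long gap
  ok_link <- c(FALSE, cand[-1] & cand[-m] & diff(pos) <= params$max_gap)
  segs <- list()
  i <- 1
  while (i <= m) {
    if (!cand[i]) { i <- i + 1; next }
    j <- i
    while (j < m && ok_link[j + 1]) j <- j + 1
    n_snps <- j - i + 1
    len <- pos[j] - pos[i] + 1
    if (n_snps >= params$min_snps && len >= params$min_length &&
        len <= n_snps * params$max_bp_per_snp) {
      segs[[length(segs) + 1]] <- data.frame(start = pos[i], end = pos[j],
                                             n_snps = n_snps, length = len)
    }
    i <- j + 1
  }
  if (length(segs) == 0) return(NULL)
  do.call(rbind, segs)
}

# Pairwise IBS by per-locus enumeration for one pair of genotype vectors.
ibs_pair_oracle <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  shared <- 2 - abs(g1[ok] - g2[ok])
  c(ibs0 = sum(shared == 0), ibs1 = sum(shared == 1),
    ibs2 = sum(shared == 2), n = sum(ok))
}

# All-pairs interval overlap count between a region table and a BED table
# (both 1-based closed).
overlap_count_oracle <- function(regions, bed) {
  cnt <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(bed))) {
      if (regions$chrom[i] == bed$chrom[j] &&
          regions$start[i] <= bed$end[j] && bed$start[j] <= regions$end[i]) {
        cnt[i] <- cnt[i] + 1L
      }
    }
  }
  cnt
}
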
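#' Simulation configuration
#'
#' Bundles and validates the parameters of the neutral haplotype simulator.
#' The simulator emulates a medium-density SNP array segregating in a single
#' population: per-SNP allele frequencies drawn from a U-shaped spectrum, and
#' local linkage disequilibrium induced by a two-pool Markov mosaic — each
#' haplotype switches between two latent "parent pools" along the chromosome
#' with a per-adjacent-SNP switch probability derived from
#' `recombination_rate` and the physical gap.
#'
#' @param n_individuals Number of diploid individuals (>= 2).
#' @param n_snps_per_chrom Number of SNPs simulated on each chromosome.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp; SNP positions are drawn
#'   uniformly (without replacement) in `1:chrom_length` and sorted.
#' @param recombination_rate Per-bp switch intensity of the latent pool
#'   mosaic; the switch probability between adjacent SNPs separated by `d` bp
#'   is `1 - exp(-recombination_rate * d)`, capped at 0.5.
#' @param maf_floor Minimum minor allele frequency in `[0, 0.5]` enforced on
#'   every simulated SNP (realized sample frequency, not just the target).
#' @param seed Integer seed; all downstream draws are reproducible from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 100, n_snps_per_chrom = 1000,
                       n_chroms = 1, chrom_length = 50e6,
                       recombination_rate = 1e-6, maf_floor = 0.05,
                       seed = 1) {
  if (!is.numeric(n_individuals) || n_individuals < 2) {
    stop("invalid sim_config field 'n_individuals': must be >= 2")
  }
  if (!is.numeric(n_snps_per_chrom) || n_snps_per_chrom < 1) {
    stop("invalid sim_config field 'n_snps_per_chrom': must be >= 1")
  }
  if (!is.numeric(n_chroms) || n_chroms < 1) {
    stop("invalid sim_config field 'n_chroms': must be >= 1")
  }
  if (!is.numeric(chrom_length) || chrom_length <= 0) {
    stop("invalid sim_config field 'chrom_length': must be > 0")
  }
  if (chrom_length < n_snps_per_chrom) {
    stop("invalid sim_config field 'chrom_length': fewer bp than SNPs")
  }
  if (!is.numeric(recombination_rate) || recombination_rate < 0) {
    stop("invalid sim_config field 'recombination_rate': must be >= 0")
  }
  if (!is.numeric(maf_floor) || maf_floor < 0 || maf_floor > 0.5) {
    stop("invalid sim_config field 'maf_floor': must be in [0, 0.5]")
  }
  if (!is.numeric(seed) || seed != round(seed)) {
    stop("invalid sim_config field 'seed': must be an integer")
  }
  structure(list(n_individuals = as.integer(n_individuals),
                 n_snps_per_chrom = as.integer(n_snps_per_chrom),
                 n_chroms = as.integer(n_chroms),
                 chrom_length = as.numeric(chrom_length),
                 recombination_rate = as.numeric(recombination_rate),
                 maf_floor = as.numeric(maf_floor),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate neutral phased haplotypes
#'
#' Generates `2 * n_individuals` phased binary haplotypes per chromosome under
#' the two-pool mosaic model of [sim_config()]. Target allele frequencies are
#' drawn from a Beta(0.45, 0.45) spectrum (U-shaped, as observed on SNP
#' arrays after ascertainment) and each pool's frequency is the target
#' perturbed by a divergence term, so that haplotypes sharing the latent pool
#' state at neighbouring SNPs are positively correlated. After generation the
#' realized minor allele count of every column is raised to the `maf_floor`
#' if sampling left it below.
#'
#' @param config A [sim_config()].
#' @return A list with `haps` (integer matrix, `2*n_individuals` rows named
#'   `<ind>_h1/<ind>_h2`) and `loci` (data frame: `chrom`, `snp`, `pos`,
#'   `allele_a`, `allele_b`, `autosomal`).
#' @export
simulate_neutral_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  H <- 2L * config$n_individuals
  m <- config$n_snps_per_chrom
  ind <- sprintf("ind%03d", seq_len(config$n_individuals))
  hap_names <- paste0(rep(ind, each = 2L), c("_h1", "_h2"))

  hap_blocks <- vector("list", config$n_chroms)
  loci_blocks <- vector("list", config$n_chroms)
  for (cc in seq_len(config$n_chroms)) {
    pos <- sort(sample.int(config$chrom_length, m))
    p <- stats::rbeta(m, 0.45, 0.45)
    p <- pmin(pmax(p, config$maf_floor), 1 - config$maf_floor)
    d <- stats::runif(m, 0, 0.18)
    p1 <- pmin(pmax(p + d, 0.01), 0.99)
    p2 <- pmin(pmax(2 * p - p1, 0.01), 0.99)

    ## latent pool state: Markov chain along the chromosome, one per haplotype
    sw <- c(0.5, pmin(0.5, 1 - exp(-config$recombination_rate * diff(pos))))
    S <- matrix(stats::rbinom(H * m, 1L, rep(sw, each = H)), H, m)
    z <- S
    for (j in seq_len(m)[-1L]) z[, j] <- z[, j - 1L] + S[, j]
    z <- z %% 2L

    PM <- matrix(p2, H, m, byrow = TRUE)
    P1 <- matrix(p1, H, m, byrow = TRUE)
    PM[z == 1L] <- P1[z == 1L]
    X <- matrix(stats::rbinom(H * m, 1L, as.vector(PM)), H, m)

    ## enforce the realized MAF floor by flipping majority alleles
    need <- ceiling(config$maf_floor * H - 1e-9)
    cnt1 <- colSums(X)
    for (j in which(pmin(cnt1, H - cnt1) < need)) {
      minor <- if (cnt1[j] <= H - cnt1[j]) 1L else 0L
      short <- need - min(cnt1[j], H - cnt1[j])
      maj_rows <- which(X[, j] != minor)
      flip <- sample(maj_rows, short)
      X[flip, j] <- minor
    }

    hap_blocks[[cc]] <- X
    loci_blocks[[cc]] <- data.frame(
      chrom = as.character(cc),
      snp = sprintf("snp%d_%d", cc, pos),
      pos = pos,
      allele_a = "A", allele_b = "B",
      autosomal = TRUE,
      stringsAsFactors = FALSE)
  }
  haps <- do.call(cbind, hap_blocks)
  storage.mode(haps) <- "integer"
  rownames(haps) <- hap_names
  loci <- do.call(rbind, loci_blocks)
  rownames(loci) <- NULL
  list(haps = haps, loci = loci)
}

#' Sweep truth record
#'
#' Describes one planted selective sweep: the chromosome, the focal position,
#' the frequency of the swept haplotype, and the flank span over which the
#' donor haplotype is copied with linearly decaying fidelity.
#'
#' @param chrom Chromosome label.
#' @param focal_position Focal position in bp.
#' @param sweep_frequency Fraction of haplotypes carrying the swept
#'   haplotype, strictly in (0, 1).
#' @param flank_span Half-width in bp of the copied flank.
#' @return A list of class `sweep_truth`.
#' @export
sweep_truth <- function(chrom, focal_position, sweep_frequency, flank_span) {
  if (sweep_frequency <= 0 || sweep_frequency >= 1) {
    stop("sweep_frequency must be strictly between 0 and 1")
  }
  if (flank_span <= 0) stop("flank_span must be > 0")
  structure(list(chrom = as.character(chrom),
                 focal_position = as.numeric(focal_position),
                 sweep_frequency = as.numeric(sweep_frequency),
                 flank_span = as.numeric(flank_span)),
            class = "sweep_truth")
}

#' Plant a selective sweep into neutral haplotypes
#'
#' Emulates the haplotype structure left by a recent incomplete sweep: a
#' fraction `sweep_frequency` of haplotypes carry one donor haplotype copied
#' over the flank `[focal - flank_span, focal + flank_span]`, with copy
#' fidelity decaying linearly from 1 at the focal SNP to 0 at the flank ends
#' (so extended haplotype homozygosity around the swept allele decays with
#' distance, as recombination would erode a real sweep). The focal column is
#' set so that exactly `round(sweep_frequency * n_haplotypes)` haplotypes
#' carry the donor (swept, "derived") allele. No entry outside the flank
#' window is modified.
#'
#' @param haps Phased haplotype matrix (rows = haplotypes).
#' @param loci Locus map matching `haps`.
#' @param truth A [sweep_truth()].
#' @param seed Integer seed for recipient choice and fidelity draws.
#' @param fidelity `"linear"` (default, decaying) or `"perfect"` (fidelity 1
#'   across the whole flank — degenerate sweep for testing).
#' @return A list with `haps` (modified matrix), `focal_snp` (name of the SNP
#'   nearest the focal position), `swept_allele` (0/1), and `carriers` (row
#'   indices of swept haplotypes).
#' @export
plant_sweep <- function(haps, loci, truth, seed = 1,
                        fidelity = c("linear", "perfect")) {
  check_haplotypes(haps, loci)
  stopifnot(inherits(truth, "sweep_truth"))
  fidelity <- match.arg(fidelity)
  idx_chr <- which(loci$chrom == truth$chrom)
  if (length(idx_chr) == 0L) stop("no loci on chromosome ", truth$chrom)
  pos_chr <- loci$pos[idx_chr]
  if (truth$focal_position < min(pos_chr) ||
      truth$focal_position > max(pos_chr)) {
    stop("focal_position ", truth$focal_position,
         " is outside the mapped span of chromosome ", truth$chrom)
  }
  in_flank <- abs(pos_chr - truth$focal_position) <= truth$flank_span
  idx <- idx_chr[in_flank]
  pos_f <- loci$pos[idx]
  focal_local <- which.min(abs(pos_f - truth$focal_position))
  focal_col <- idx[focal_local]

  set.seed(seed)
  H <- nrow(haps)
  n_car <- round(truth$sweep_frequency * H)
  recipients <- sample.int(H, n_car)
  donor <- haps[recipients[1L], idx]
  fid <- if (fidelity == "perfect") rep(1, length(idx)) else {
    pmax(0, 1 - abs(pos_f - truth$focal_position) / truth$flank_span)
  }
  for (r in recipients) {
    copy <- stats::runif(length(idx)) < fid
    haps[r, idx[copy]] <- donor[copy]
  }
  swept <- donor[focal_local]
  haps[recipients, focal_col] <- swept
  haps[-recipients, focal_col] <- 1L - swept
  list(haps = haps, focal_snp = loci$snp[focal_col],
       swept_allele = swept, carriers = sort(recipients))
}

## Validate a tract truth table: individual, chrom, start, end; tracts of one
## individual must not overlap on a chromosome.
check_tracts <- function(tracts) {
  stopifnot(is.data.frame(tracts))
  need <- c("individual", "chrom", "start", "end")
  if (!all(need %in% names(tracts))) {
    stop("tract table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tracts$start >= tracts$end)) {
    stop("tract start must be < end")
  }
  for (key in split(tracts, paste(tracts$individual, tracts$chrom))) {
    if (nrow(key) < 2L) next
    key <- key[order(key$start), ]
    if (any(key$start[-1L] <= key$end[-nrow(key)])) {
      stop("overlapping autozygous tracts for individual ",
           key$individual[1L], " on chromosome ", key$chrom[1L])
    }
  }
  invisible(tracts)
}

#' Build diploid genotypes with planted autozygous tracts
#'
#' Pairs consecutive haplotype rows into individuals and codes genotypes as
#' the sum of the two parental alleles (copies of allele B: 0/1/2). Within
#' each truth tract the second haplotype is overwritten by the first, forcing
#' homozygosity over the tract — the autozygosity that runs-of-homozygosity
#' detection should recover. Missing genotypes are then injected uniformly at
#' `missing_rate`, by default sparing tract cells so planted truth is not
#' eroded.
#'
#' @param haps Phased haplotype matrix (rows = haplotypes, 2 per individual).
#' @param loci Locus map matching `haps`.
#' @param tracts Data frame (`individual`, `chrom`, `start`, `end`) of
#'   planted autozygous tracts, or `NULL` for none. `individual` labels must
#'   match the haplotype row-name prefixes (e.g. `ind007`).
#' @param missing_rate Per-cell missingness probability in `[0, 1)`.
#' @param seed Integer seed for the missingness mask.
#' @param protect_tracts If `TRUE` (default), no missing calls are injected
#'   inside planted tracts.
#' @return Integer genotype matrix (individuals x SNPs) with `NA` for
#'   missing, row names = individual labels.
#' @export
make_inbred_genotypes <- function(haps, loci, tracts = NULL,
                                  missing_rate = 0, seed = 1,
                                  protect_tracts = TRUE) {
  check_haplotypes(haps, loci)
  n <- nrow(haps) %/% 2L
  ind <- if (is.null(rownames(haps))) sprintf("ind%03d", seq_len(n)) else {
    sub("_h[12]$", "", rownames(haps)[seq(1L, 2L * n, by = 2L)])
  }
  h1 <- haps[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  h2 <- haps[seq(2L, 2L * n, by = 2L), , drop = FALSE]

  tract_mask <- NULL
  if (!is.null(tracts) && nrow(tracts) > 0L) {
    check_tracts(tracts)
    unknown <- setdiff(tracts$individual, ind)
    if (length(unknown) > 0L) {
      stop("tract individual(s) not in haplotype set: ",
           paste(unknown, collapse = ", "))
    }
    tract_mask <- matrix(FALSE, n, ncol(haps))
    for (k in seq_len(nrow(tracts))) {
      i <- match(tracts$individual[k], ind)
      cols <- which(loci$chrom == tracts$chrom[k] &
                    loci$pos >= tracts$start[k] &
                    loci$pos <= tracts$end[k])
      h2[i, cols] <- h1[i, cols]
      tract_mask[i, cols] <- TRUE
    }
  }

  g <- h1 + h2
  if (missing_rate > 0) {
    set.seed(seed)
    drop <- matrix(stats::runif(length(g)) < missing_rate, n, ncol(g))
    if (protect_tracts && !is.null(tract_mask)) drop[tract_mask] <- FALSE
    g[drop] <- NA_integer_
  }
  storage.mode(g) <- "integer"
  rownames(g) <- ind
  colnames(g) <- loci$snp
  g
}

#' Write truth records as TSV
#'
#' @param truths For sweeps: a list of [sweep_truth()] records. For tracts:
#'   the tract data frame itself.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @rdname truth-io
#' @export
write_sweep_truth <- function(truths, path) {
  if (inherits(truths, "sweep_truth")) truths <- list(truths)
  df <- do.call(rbind, lapply(truths, function(t) {
    data.frame(chrom = t$chrom, focal_pos = t$focal_position,
               freq = t$sweep_frequency, span = t$flank_span)
  }))
  write_tsv(df, path)
}

#' @rdname truth-io
#' @export
write_tract_truth <- function(truths, path) {
  check_tracts(truths)
  write_tsv(truths[, c("individual", "chrom", "start", "end")], path)
}
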
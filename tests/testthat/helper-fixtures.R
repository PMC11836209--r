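# Shared fixture builders (all seeded by the caller).

# Small neutral cohort: haplotypes + loci.
small_sim <- function(n_ind = 20, n_snps = 200, n_chroms = 1,
                      chrom_length = 10e6, maf_floor = 0.05, seed = 1) {
  simulate_neutral_haplotypes(sim_config(
    n_individuals = n_ind, n_snps_per_chrom = n_snps, n_chroms = n_chroms,
    chrom_length = chrom_length, maf_floor = maf_floor, seed = seed))
}

# Evenly spaced locus map on one chromosome.
even_loci <- function(m, spacing = 25e3, chrom = "1") {
  pos <- seq(spacing, by = spacing, length.out = m)
  data.frame(chrom = chrom, snp = sprintf("snp%s_%d", chrom, pos), pos = pos,
             allele_a = "A", allele_b = "B", autosomal = TRUE,
             stringsAsFactors = FALSE)
}

# Genotype matrix from explicit rows (list of vectors), with even loci.
geno_fixture <- function(rows, spacing = 25e3) {
  g <- do.call(rbind, rows)
  storage.mode(g) <- "integer"
  rownames(g) <- sprintf("ind%03d", seq_len(nrow(g)))
  list(g = g, loci = even_loci(ncol(g), spacing))
}

# Random haplotype fixture for EHH oracle checks: moderate LD via the
# package simulator, occasionally with duplicated rows to create shared
# haplotypes.
ehh_fixture <- function(seed) {
  set.seed(seed)
  n_ind <- sample(3:10, 1)           # 6..20 haplotypes
  m <- sample(10:50, 1)
  sim <- small_sim(n_ind = n_ind, n_snps = m, chrom_length = 5e6,
                   maf_floor = 0, seed = seed)
  haps <- sim$haps
  if (stats::runif(1) < 0.5) {       # force some identical haplotypes
    dup <- sample(nrow(haps), 2)
    haps[dup[2], ] <- haps[dup[1], ]
  }
  list(haps = haps, loci = sim$loci)
}
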
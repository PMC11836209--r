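#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# Builds a synthetic single-population cohort emulating a medium-density
# SNP-array design: 120 individuals, 3 chromosomes of 100 Mb with 3,000
# SNPs each (~33 kb spacing), MAF floor 0.05. Planted truth:
#   * one selective sweep on chromosome 2 at 50 Mb (swept-haplotype
#     frequency 0.5, 2 Mb flank) — the iHS target;
#   * a 6 Mb autozygous tract on chromosome 2 (47–53 Mb) shared by 30% of
#     individuals — a ROH island overlapping the sweep, mirroring the
#     iHS/ROH agreement a real scan looks for;
#   * a 5 Mb tract on chromosome 3 (20–25 Mb) shared by a different 30% —
#     a ROH-only signature;
#   * per-individual private tracts of 2–20 Mb at three inbreeding levels —
#     the F_ROH/F_HOM gradient.
# Writes PED/MAP, a phased VCF, truth TSVs, and a synthetic gene BED.

suppressPackageStartupMessages(library(ovisweep))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if ("--seed" %in% args) args[match("--seed", args) + 1] else "1")
out <- if ("--out" %in% args) args[match("--out", args) + 1] else "results"
data_dir <- file.path(out, "data")
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_individuals = 120, n_snps_per_chrom = 3000,
                  n_chroms = 3, chrom_length = 100e6,
                  recombination_rate = 1e-6, maf_floor = 0.05, seed = seed)
sim <- simulate_neutral_haplotypes(cfg)
cat(sprintf("simulated %d haplotypes x %d SNPs on %d chromosomes\n",
            nrow(sim$haps), ncol(sim$haps), cfg$n_chroms))

## planted sweep (chr2 @ 50 Mb, frequency 0.5, 2 Mb flank)
sweep <- sweep_truth("2", 50e6, 0.5, 2e6)
sw <- plant_sweep(sim$haps, sim$loci, sweep, seed = seed + 1)
haps <- sw$haps
cat(sprintf("planted sweep: focal SNP %s, %d carrier haplotypes\n",
            sw$focal_snp, length(sw$carriers)))

## planted autozygosity
ind <- sprintf("ind%03d", seq_len(cfg$n_individuals))
set.seed(seed + 2)
shared_a <- sample(ind, 36)                       # 30%: chr2 island (sweep)
shared_b <- sample(ind, 36)                       # 30%: chr3 island
tracts <- rbind(
  data.frame(individual = shared_a, chrom = "2", start = 47e6, end = 53e6),
  data.frame(individual = shared_b, chrom = "3", start = 20e6, end = 25e6))
private <- data.frame(individual = ind[1:60], chrom = "1",
                      start = stats::runif(60, 1e6, 70e6))
private$end <- private$start +
  rep(c(2e6, 8e6, 20e6), each = 20)               # three inbreeding levels
tracts <- rbind(tracts, private)
g <- make_inbred_genotypes(haps, sim$loci, tracts, missing_rate = 0.02,
                           seed = seed + 3)
cat(sprintf("built %d x %d genotype matrix with %d planted tracts\n",
            nrow(g), ncol(g), nrow(tracts)))

write_ped_map(g, sim$loci, file.path(data_dir, "cohort.ped"),
              file.path(data_dir, "cohort.map"))
write_phased_vcf(haps, sim$loci, file.path(data_dir, "cohort_phased.vcf"))
write_sweep_truth(sweep, file.path(data_dir, "truth_sweeps.tsv"))
write_tract_truth(tracts, file.path(data_dir, "truth_tracts.tsv"))

## synthetic gene annotation: intervals near the planted signals + decoys
## (coordinates are BED 0-based half-open)
genes <- c("2\t48999999\t49600000\tGENE_SWEEP_A",
           "2\t49900000\t50400000\tGENE_SWEEP_B",
           "2\t52000000\t52800000\tGENE_ISLAND2",
           "3\t21500000\t22500000\tGENE_ISLAND3",
           "1\t10000000\t10800000\tGENE_DECOY1",
           "3\t80000000\t80500000\tGENE_DECOY2")
writeLines(genes, file.path(data_dir, "genes_synthetic.bed"))
cat("stage 1 outputs written under", data_dir, "\n")
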
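#!/usr/bin/env Rscript
# Stage 2 — genotype QC and genetic-diversity statistics.
#
# Reads the PED/MAP cohort from stage 1, applies the array QC chain
# (autosomes; sample call rate >= 90%; SNP call rate >= 90%; MAF >= 0.05),
# then computes the diversity panel: MAF spectrum over 7 classes, proportion
# of polymorphic SNPs, Ho/He, pairwise identity-by-state distance D, and
# per-individual F_HOM.

suppressPackageStartupMessages(library(ovisweep))
args <- commandArgs(trailingOnly = TRUE)
out <- if ("--out" %in% args) args[match("--out", args) + 1] else "results"
data_dir <- file.path(out, "data")
if (!file.exists(file.path(data_dir, "cohort.ped"))) {
  stop("missing ", file.path(data_dir, "cohort.ped"),
       " - run analysis/01_simulate.R first")
}

raw <- read_ped_map(file.path(data_dir, "cohort.ped"),
                    file.path(data_dir, "cohort.map"))
qc <- qc_filter(raw$genotypes, raw$loci)
print(qc$report)
write_tsv(as.data.frame(qc$report), file.path(out, "qc_report.tsv"))

g <- qc$genotypes
sp <- maf_spectrum(g)
write_tsv(data.frame(class = names(sp$histogram),
                     n_snps = as.integer(sp$histogram)),
          file.path(out, "maf_classes.tsv"))

hh <- ho_he(g)
pd <- pairwise_distance(g)
fh <- f_hom(g)
write_tsv(data.frame(individual = names(fh), f_hom = fh),
          file.path(out, "f_hom.tsv"))
write_tsv(pd$pairs, file.path(out, "pairwise_ibs.tsv"))

ds <- diversity_summary(g)
write_tsv(ds, file.path(out, "diversity_summary.tsv"))
cat(sprintf(
  "diversity: MAF %.3f+/-%.3f  P_N %.3f  Ho %.3f  He %.3f  D %.3f  F_HOM %.3f\n",
  ds$maf_mean, ds$maf_sd, ds$p_n, ds$ho_mean, ds$he_mean, ds$d_mean,
  ds$fhom_mean))
cat(sprintf("%d of %d individuals have negative F_HOM\n",
            sum(fh < 0, na.rm = TRUE), length(fh)))

## post-QC genotypes for downstream stages
write_ped_map(g, qc$loci, file.path(data_dir, "cohort_qc.ped"),
              file.path(data_dir, "cohort_qc.map"))
cat("stage 2 outputs written under", out, "\n")
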
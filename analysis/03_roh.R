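#!/usr/bin/env Rscript
# Stage 3 — runs of homozygosity, genomic inbreeding and ROH islands.
#
# Computes the minimum-SNP window from the false-positive bound, detects ROH
# by sliding window (<=1 het, <=2 missing per window; 1 Mb gap and length
# floors; >=1 SNP/100 kb), classifies runs into the five length classes,
# derives F_ROH and its correlation with F_HOM, and calls ROH islands where
# at least 10% of individuals share a run.

suppressPackageStartupMessages(library(ovisweep))
args <- commandArgs(trailingOnly = TRUE)
out <- if ("--out" %in% args) args[match("--out", args) + 1] else "results"
data_dir <- file.path(out, "data")
if (!file.exists(file.path(data_dir, "cohort_qc.ped"))) {
  stop("missing ", file.path(data_dir, "cohort_qc.ped"),
       " - run analysis/02_qc_diversity.R first")
}

qc <- read_ped_map(file.path(data_dir, "cohort_qc.ped"),
                   file.path(data_dir, "cohort_qc.map"))
g <- qc$genotypes
loci <- qc$loci

het_mean <- mean(ho_he(g)$ho, na.rm = TRUE)
L <- min_snp_threshold(a = 0.05, n_s = ncol(g), n_i = nrow(g),
                       het = het_mean)
cat(sprintf("minimum SNPs per window/run: %d (het = %.3f)\n", L, het_mean))

pars <- roh_params(min_snps = L)
segs <- detect_roh(g, loci, pars)
write_tsv(segs, file.path(out, "roh_segments.tsv"))
cat(sprintf("detected %d ROH in %d individuals\n",
            nrow(segs), length(unique(segs$individual))))
per_chrom <- sort(table(segs$chrom), decreasing = TRUE)
cat(sprintf("most/fewest ROH per chromosome: %s (n=%d) / %s (n=%d)\n",
            names(per_chrom)[1], per_chrom[1],
            names(per_chrom)[length(per_chrom)],
            per_chrom[length(per_chrom)]))

tab <- classify_roh(segs, loci, rownames(g))
write_tsv(tab, file.path(out, "roh_classes.tsv"))
print(tab)

froh <- f_roh(segs, loci, rownames(g))
write_tsv(data.frame(individual = names(froh), f_roh = froh),
          file.path(out, "f_roh.tsv"))

fhom_tab <- utils::read.delim(file.path(out, "f_hom.tsv"))
r <- correlate_inbreeding(froh[fhom_tab$individual], fhom_tab$f_hom)
cat(sprintf("F_ROH %.4f+/-%.4f; Pearson r(F_ROH, F_HOM) = %.3f\n",
            mean(froh), stats::sd(froh), r))
write_tsv(data.frame(stat = c("froh_mean", "froh_sd", "r_froh_fhom"),
                     value = c(mean(froh), stats::sd(froh), r)),
          file.path(out, "inbreeding_summary.tsv"))

inc <- snp_roh_incidence(segs, loci, nrow(g))
write_tsv(data.frame(loci[, c("chrom", "snp", "pos")], incidence = inc),
          file.path(out, "roh_incidence.tsv"))

islands <- roh_islands(inc, loci, threshold = 0.10)
write_tsv(islands, file.path(out, "roh_islands.tsv"))
write_bed(islands, file.path(out, "roh_islands.bed"))
cat(sprintf("called %d ROH island(s):\n", nrow(islands)))
if (nrow(islands)) print(islands[, c("chrom", "start", "end", "n_snps")])
cat("stage 3 outputs written under", out, "\n")
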
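#!/usr/bin/env Rscript
# Stage 5 — region calling, method overlap, annotation.
#
# Tiles the genome into non-overlapping 500-kb windows, calls iHS regions
# (>=10 scored SNPs of which >=5 extreme, adjacent called windows merged),
# intersects them with the ROH islands from stage 3, and annotates all
# regions against the synthetic gene BED from stage 1.

suppressPackageStartupMessages(library(ovisweep))
args <- commandArgs(trailingOnly = TRUE)
out <- if ("--out" %in% args) args[match("--out", args) + 1] else "results"
data_dir <- file.path(out, "data")
for (f in c("ihs_major.tsv", "roh_islands.tsv")) {
  if (!file.exists(file.path(out, f))) {
    stop("missing ", file.path(out, f),
         " - run analysis/03_roh.R and analysis/04_ihs.R first")
  }
}

ihs <- utils::read.delim(file.path(out, "ihs_major.tsv"),
                         colClasses = c(chrom = "character"))
islands <- utils::read.delim(file.path(out, "roh_islands.tsv"),
                             colClasses = c(chrom = "character"))
bed_path <- file.path(data_dir, "genes_synthetic.bed")

regions <- call_ihs_regions(ihs, window_size = 5e5,
                            min_snps = 10, min_extreme = 5)
regions <- annotate_intervals(regions, bed_path)
write_tsv(regions, file.path(out, "ihs_regions.tsv"))
write_bed(regions, file.path(out, "ihs_regions.bed"))
cat(sprintf("iHS approach: %d region(s) under selection\n", nrow(regions)))
if (nrow(regions)) {
  print(regions[, c("chrom", "start", "end", "n_snps", "n_extreme",
                    "peak_snp", "peak_value", "annotations")])
}

islands_ann <- annotate_intervals(islands, bed_path)
write_tsv(islands_ann, file.path(out, "roh_islands_annotated.tsv"))

ov <- overlap_regions(regions, islands)
if (nrow(ov)) {
  ov <- annotate_intervals(ov, bed_path)
  cat(sprintf("methods agree on %d region(s):\n", nrow(ov)))
  print(ov[, c("chrom", "start", "end", "annotations")])
} else {
  cat("no overlap between iHS regions and ROH islands\n")
}
write_tsv(ov, file.path(out, "method_overlap.tsv"))
cat("stage 5 outputs written under", out, "\n")
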
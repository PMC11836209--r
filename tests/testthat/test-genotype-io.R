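test_that("PED alleles are recoded as counts of the lexically later allele", {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(c("1\tsnpA\t0\t1000", "1\tsnpB\t0\t2000"), map)
  writeLines("F1 I1 0 0 1 -9 A A G A", ped)
  out <- read_ped_map(ped, map)
  # snpA: alleles A/A, only A observed -> homozygous (2 copies of allele B=A)
  # snpB: G/A observed, allele B = G (lexically later), genotype het = 1
  expect_equal(unname(out$genotypes[1, ]), c(2L, 1L))
  expect_equal(out$loci$allele_b, c("A", "G"))
})

test_that("'0 0' and half-missing allele pairs become missing", {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(c("1\tsnpA\t0\t1000"), map)
  writeLines(c("F1 I1 0 0 1 -9 0 0", "F1 I2 0 0 1 -9 A 0",
               "F1 I3 0 0 1 -9 A C"), ped)
  out <- read_ped_map(ped, map)
  expect_true(is.na(out$genotypes["I1", 1]))
  expect_true(is.na(out$genotypes["I2", 1]))
  expect_equal(unname(out$genotypes["I3", 1]), 1L)
})

test_that("ragged PED rows and >2 alleles are rejected with context", {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(c("1\tsnpA\t0\t1000"), map)
  writeLines(c("F1 I1 0 0 1 -9 A A", "F1 I2 0 0 1 -9 A"), ped)
  expect_error(read_ped_map(ped, map), "line 2")
  writeLines(c("F1 I1 0 0 1 -9 A C", "F1 I2 0 0 1 -9 G T"), ped)
  expect_error(read_ped_map(ped, map), "snpA")
})

test_that("PED/MAP round-trips reproduce the genotype matrix exactly", {
  sim <- small_sim(n_ind = 15, n_snps = 60, n_chroms = 2, seed = 11)
  g <- make_inbred_genotypes(sim$haps, sim$loci, missing_rate = 0.05,
                             seed = 3)
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  write_ped_map(g, sim$loci, ped, map)
  back <- read_ped_map(ped, map)
  expect_identical(back$genotypes, g)
  expect_equal(back$loci$snp, sim$loci$snp)
  expect_equal(back$loci$pos, sim$loci$pos)
})

test_that("phased VCF round-trips the haplotype matrix", {
  sim <- small_sim(n_ind = 3, n_snps = 2, seed = 12)
  path <- tempfile(fileext = ".vcf")
  write_phased_vcf(sim$haps, sim$loci, path)
  back <- read_phased_vcf(path)
  expect_equal(dim(back$haps), c(6L, 2L))
  expect_equal(unname(back$haps), unname(sim$haps))
  expect_equal(back$loci$pos, sim$loci$pos)

  # GT "0|1" maps to haplotype rows 0 then 1
  gt_line <- readLines(path)
  body <- gt_line[!startsWith(gt_line, "#")]
  f <- strsplit(body[1], "\t")[[1]]
  expect_equal(as.integer(strsplit(f[10], "|", fixed = TRUE)[[1]]),
               unname(sim$haps[1:2, 1]))
})

test_that("unphased and multiallelic VCF records are rejected", {
  sim <- small_sim(n_ind = 3, n_snps = 4, seed = 13)
  path <- tempfile(fileext = ".vcf")
  write_phased_vcf(sim$haps, sim$loci, path)
  lines <- readLines(path)
  bad <- sub("(\tGT\t[01])\\|", "\\1/", lines[length(lines)])
  writeLines(c(lines[-length(lines)], bad), path)
  expect_error(read_phased_vcf(path), "phase")

  write_phased_vcf(sim$haps, sim$loci, path)
  lines <- readLines(path)
  i <- length(lines)
  f <- strsplit(lines[i], "\t")[[1]]
  f[5] <- "B,C"
  writeLines(c(lines[-i], paste(f, collapse = "\t")), path)
  expect_error(read_phased_vcf(path), f[3])
})

test_that("QC filters apply thresholds in order with an additive report", {
  # 10 samples, 12 SNPs: one non-autosomal, one monomorphic (MAF 0), one
  # with call rate 0.7, one with MAF 0.2, eight well-behaved het columns
  # (each sample misses at most 1 of 11 autosomal SNPs, so no sample drops)
  g <- cbind(rep(0L, 10),                       # chrX, would pass otherwise
             rep(0L, 10),                       # monomorphic, MAF 0
             c(rep(NA_integer_, 3), rep(1L, 7)),# call rate 0.7 < 0.9
             c(rep(1L, 4), rep(0L, 6)),         # MAF 0.2
             matrix(1L, 10, 8))                 # MAF 0.5
  rownames(g) <- sprintf("ind%03d", 1:10)
  loci <- even_loci(12)
  loci$chrom <- c("X", rep("1", 11))
  loci$snp <- sprintf("s%02d", 1:12)
  out <- qc_filter(g, loci)
  expect_equal(out$report$removed_nonautosomal, 1)
  expect_equal(out$report$removed_sample_callrate, 0)
  expect_equal(out$report$removed_snp_callrate, 1)
  expect_equal(out$report$removed_maf, 1)
  expect_equal(ncol(out$genotypes), 9L)
  # additivity of the SNP ledger
  r <- out$report
  expect_equal(r$n_snps_out,
               r$n_snps_in - r$removed_nonautosomal -
                 r$removed_snp_callrate - r$removed_maf)
})

test_that("samples below the genotyping-rate threshold are dropped", {
  sim <- small_sim(n_ind = 10, n_snps = 100, seed = 14)
  g <- make_inbred_genotypes(sim$haps, sim$loci, missing_rate = 0)
  g[1, 1:20] <- NA_integer_        # sample call rate 0.8
  out <- qc_filter(g, sim$loci, maf_min = 0)
  expect_equal(out$report$removed_sample_callrate, 1)
  expect_false("ind001" %in% rownames(out$genotypes))
})

test_that("QC is idempotent and every retained SNP passes a direct recount", {
  sim <- small_sim(n_ind = 40, n_snps = 300, maf_floor = 0, seed = 15)
  g <- make_inbred_genotypes(sim$haps, sim$loci, missing_rate = 0.08,
                             seed = 5)
  once <- qc_filter(g, sim$loci)
  twice <- qc_filter(once$genotypes, once$loci)
  expect_identical(twice$genotypes, once$genotypes)
  expect_equal(twice$report$removed_maf +
                 twice$report$removed_snp_callrate +
                 twice$report$removed_sample_callrate, 0)

  # direct recount oracle on retained SNPs
  gk <- once$genotypes
  n <- colSums(!is.na(gk))
  p <- colSums(gk, na.rm = TRUE) / (2 * n)
  expect_true(all(pmin(p, 1 - p) >= 0.05))
  expect_true(all(n / nrow(gk) >= 0.9))
})

test_that("QC hard-errors when a filter empties the dataset", {
  g <- matrix(0L, 4, 3)
  rownames(g) <- sprintf("ind%03d", 1:4)
  loci <- even_loci(3)
  expect_error(qc_filter(g, loci), "all SNPs")
})
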
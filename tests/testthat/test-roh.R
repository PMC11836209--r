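test_that("minimum-SNP threshold evaluates the false-positive bound", {
  # trivial closed form: ln(0.5)/ln(0.5) = 1
  expect_equal(min_snp_threshold(0.5, 1, 1, 0.5), 1L)
  # raw value before rounding up, frozen from a direct evaluation of
  # log(a/(n_s*n_i))/log(1-het)
  expect_equal(min_snp_threshold(0.05, 45943, 514, 0.388, raw = TRUE),
               40.6765, tolerance = 1e-4)
  expect_error(min_snp_threshold(0.05, 100, 10, 1.2), "het")
})

test_that("an all-heterozygous individual yields no runs", {
  fx <- geno_fixture(list(rep(1L, 200)))
  pars <- roh_params(min_snps = 20)
  expect_equal(nrow(detect_roh(fx$g, fx$loci, pars)), 0L)
})

test_that("short homozygous stretches below the length floor are dropped", {
  # 0.5 Mb homozygous stretch (21 SNPs at 25 kb) inside het background
  gi <- rep(1L, 200)
  gi[90:110] <- 0L
  fx <- geno_fixture(list(gi))
  pars <- roh_params(min_snps = 15, min_length = 1e6)
  expect_equal(nrow(detect_roh(fx$g, fx$loci, pars)), 0L)
})

test_that("a planted 3 Mb tract is recovered with near-truth boundaries", {
  sim <- small_sim(n_ind = 10, n_snps = 400, chrom_length = 10e6, seed = 40)
  tracts <- data.frame(individual = "ind002", chrom = "1",
                       start = 4e6, end = 7e6)
  g <- make_inbred_genotypes(sim$haps, sim$loci, tracts, missing_rate = 0)
  pars <- roh_params(min_snps = 41)
  segs <- detect_roh(g, sim$loci, pars)
  segs <- segs[segs$individual == "ind002", ]
  expect_equal(nrow(segs), 1L)
  window_bp <- pars$min_snps * stats::median(diff(sim$loci$pos))
  expect_lt(abs(segs$start - 4e6), window_bp)
  expect_lt(abs(segs$end - 7e6), window_bp)
})

test_that("every emitted segment satisfies the declared constraints", {
  sim <- small_sim(n_ind = 25, n_snps = 500, chrom_length = 12e6, seed = 41)
  tracts <- do.call(rbind, lapply(c(3, 9, 17), function(i) {
    data.frame(individual = sprintf("ind%03d", i), chrom = "1",
               start = 2e6 + i * 1e5, end = 6e6 + i * 1e5)
  }))
  g <- make_inbred_genotypes(sim$haps, sim$loci, tracts,
                             missing_rate = 0.02, seed = 6)
  pars <- roh_params(min_snps = 35)
  segs <- detect_roh(g, sim$loci, pars)
  expect_gt(nrow(segs), 0L)
  for (k in seq_len(nrow(segs))) {
    idx <- which(sim$loci$chrom == segs$chrom[k] &
                 sim$loci$pos >= segs$start[k] &
                 sim$loci$pos <= segs$end[k])
    expect_equal(length(idx), segs$n_snps[k])
    expect_gte(segs$n_snps[k], pars$min_snps)
    expect_gte(segs$length[k], pars$min_length)
    expect_lte(max(diff(sim$loci$pos[idx])), pars$max_gap)
    expect_lte(segs$length[k], segs$n_snps[k] * pars$max_bp_per_snp)
  }
})

test_that("sliding-window scanner equals the exhaustive-interval oracle", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- sample(80:300, 1)
    sim <- small_sim(n_ind = 6, n_snps = m, chrom_length = 8e6, seed = seed)
    tracts <- data.frame(individual = c("ind001", "ind004"), chrom = "1",
                         start = c(1e6, 4e6), end = c(4.5e6, 7.5e6))
    g <- make_inbred_genotypes(sim$haps, sim$loci, tracts,
                               missing_rate = 0.03, seed = seed)
    pars <- roh_params(min_snps = sample(15:41, 1))
    segs <- detect_roh(g, sim$loci, pars)
    for (i in seq_len(nrow(g))) {
      o <- roh_exhaustive_oracle(g[i, ], sim$loci$pos, pars)
      s <- segs[segs$individual == rownames(g)[i], , drop = FALSE]
      if (is.null(o)) {
        expect_equal(nrow(s), 0L)
      } else {
        expect_equal(nrow(s), nrow(o))
        expect_equal(s$start, o$start)
        expect_equal(s$end, o$end)
        expect_equal(s$n_snps, o$n_snps)
      }
    }
  }
})

test_that("length classes bin, count and sum to 100 percent", {
  loci <- even_loci(100, spacing = 1e6)
  segs <- data.frame(individual = c("a", "b", "c"), chrom = "1",
                     start = 1e6, end = c(3e6, 8e6, 56e6),
                     n_snps = 50, length = c(2e6, 7e6, 55e6))
  tab <- classify_roh(segs, loci, individuals = c("a", "b", "c"))
  expect_equal(tab$n, c(1L, 1L, 0L, 0L, 1L))
  expect_equal(sum(tab$percent), 100)

  segs3 <- transform(segs, end = 4e6, length = 3e6)
  tab3 <- classify_roh(segs3, loci, individuals = c("a", "b", "c"))
  expect_equal(tab3$percent[1], 100)
})

test_that("F_ROH spans its fixed points and never decreases with a new tract", {
  loci <- even_loci(101, spacing = 1e5)   # one 10 Mb chromosome
  none <- data.frame(individual = character(), chrom = character(),
                     start = numeric(), end = numeric(),
                     n_snps = integer(), length = numeric())
  expect_equal(unname(f_roh(none, loci, "ind001")), 0)

  whole <- data.frame(individual = "ind001", chrom = "1",
                      start = min(loci$pos), end = max(loci$pos),
                      n_snps = 101, length = max(loci$pos) - min(loci$pos))
  expect_equal(unname(f_roh(whole, loci, "ind001")), 1)

  part <- data.frame(individual = "ind001", chrom = "1",
                     start = 1e5, end = 3e6, n_snps = 30, length = 2.9e6)
  extra <- rbind(part, data.frame(individual = "ind001", chrom = "1",
                                  start = 5e6, end = 6e6, n_snps = 11,
                                  length = 1e6))
  expect_gt(unname(f_roh(extra, loci, "ind001")),
            unname(f_roh(part, loci, "ind001")))
})

test_that("inbreeding correlation hits its fixed points", {
  f <- c(0.01, 0.05, 0.2, 0.12)
  expect_equal(correlate_inbreeding(f, f), 1)
  expect_equal(correlate_inbreeding(f, -f), -1)
  expect_warning(r <- correlate_inbreeding(f, rep(0.1, 4)), "variance")
  expect_true(is.na(r))
})

test_that("SNP incidence counts covering individuals and stays in [0,1]", {
  loci <- even_loci(50, spacing = 1e5)
  segs <- data.frame(individual = "ind001", chrom = "1",
                     start = 1e6, end = 2e6, n_snps = 11, length = 1e6 + 1)
  inc <- snp_roh_incidence(segs, loci, n_individuals = 10)
  expect_equal(inc[loci$pos == 1.5e6], 0.1)
  expect_equal(inc[loci$pos == 4e6], 0)
  sim <- small_sim(n_ind = 15, n_snps = 300, seed = 42)
  tracts <- data.frame(individual = sprintf("ind%03d", 1:6), chrom = "1",
                       start = 2e6, end = 8e6)
  g <- make_inbred_genotypes(sim$haps, sim$loci, tracts, missing_rate = 0)
  segs2 <- detect_roh(g, sim$loci, roh_params(min_snps = 41))
  inc2 <- snp_roh_incidence(segs2, sim$loci, 15)
  expect_true(all(inc2 >= 0 & inc2 <= 1))
})

test_that("ROH islands use an inclusive threshold and recover shared tracts", {
  loci <- even_loci(10, spacing = 1e5)
  inc <- c(0, 0, 0.10, 0.12, 0.10, 0, 0.05, 0, 0.2, 0)
  isl <- roh_islands(inc, loci, threshold = 0.10)
  expect_equal(nrow(isl), 2L)           # exactly-0.10 SNPs included
  expect_equal(isl$n_snps, c(3L, 1L))
  expect_equal(nrow(roh_islands(rep(0.05, 10), loci)), 0L)

  # 30% of individuals share a tract -> island containing the tract midpoint
  sim <- small_sim(n_ind = 20, n_snps = 400, chrom_length = 10e6, seed = 43)
  tracts <- data.frame(individual = sprintf("ind%03d", 1:6), chrom = "1",
                       start = 3e6, end = 6e6)
  g <- make_inbred_genotypes(sim$haps, sim$loci, tracts, missing_rate = 0)
  segs <- detect_roh(g, sim$loci, roh_params(min_snps = 41))
  inc2 <- snp_roh_incidence(segs, sim$loci, 20)
  isl2 <- roh_islands(inc2, sim$loci, 0.10)
  expect_true(any(isl2$start <= 4.5e6 & isl2$end >= 4.5e6))
})
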
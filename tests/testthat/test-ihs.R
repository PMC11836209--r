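test_that("ancestral assignment follows frequency, tie rule and seed", {
  # freq(allele 1) = 0.8 -> ancestral 1; exact tie -> allele 0
  haps <- rbind(c(1L, 1L), c(1L, 0L), c(1L, 1L), c(1L, 0L), c(0L, 1L),
                c(1L, 0L), c(1L, 1L), c(1L, 0L), c(1L, 1L), c(0L, 0L))
  anc <- assign_ancestral(haps, "major")
  expect_equal(anc, c(1L, 0L))

  sim <- small_sim(n_ind = 10, n_snps = 40, seed = 50)
  r1 <- assign_ancestral(sim$haps, "random", seed = 99)
  r2 <- assign_ancestral(sim$haps, "random", seed = 99)
  expect_identical(r1, r2)

  mono <- cbind(rep(1L, 8), c(rep(0L, 4), rep(1L, 4)))
  expect_true(is.na(assign_ancestral(mono, "major")[1]))
})

test_that("EHH matches enumerated pair counting at a hand example", {
  # 4 carriers: two identical from focal to x, two singletons -> 1/6
  haps <- rbind(c(1L, 0L, 0L), c(1L, 0L, 0L),
                c(1L, 1L, 0L), c(1L, 0L, 1L),
                c(0L, 0L, 0L), c(0L, 0L, 0L))
  loci <- even_loci(3, spacing = 1e5)
  curve <- ehh(haps, loci, 1, 1L, cutoff = 0)
  expect_equal(curve$curve$ehh[curve$curve$pos == loci$pos[1]], 1)
  expect_equal(curve$curve$ehh[curve$curve$pos == loci$pos[2]],
               choose(3, 2) / choose(4, 2))   # groups {1,2,4} and {3}
  expect_equal(curve$curve$ehh[curve$curve$pos == loci$pos[3]],
               1 / 6)                          # only haplotypes 1,2 identical
})

test_that("two identical haplotypes keep EHH at 1 end to end", {
  sim <- small_sim(n_ind = 6, n_snps = 30, seed = 51)
  haps <- sim$haps
  haps[2, ] <- haps[1, ]
  al <- haps[1, 15]
  haps[-c(1, 2), 15] <- 1L - al    # rows 1,2 are the only carriers
  curve <- ehh(haps, sim$loci, 15, al, cutoff = 0)
  expect_true(all(curve$curve$ehh == 1))
  expect_true(curve$truncated_left && curve$truncated_right)
})

test_that("grouped EHH equals the brute-force pairwise oracle", {
  for (seed in 1:25) {
    fx <- ehh_fixture(seed)
    set.seed(seed + 1000)
    j <- sample(ncol(fx$haps), 1)
    al <- sample(0:1, 1)
    if (sum(fx$haps[, j] == al) < 2) next
    curve <- ehh(fx$haps, fx$loci, j, al)
    o <- ehh_pairwise_oracle(fx$haps, fx$loci$pos, j, al)
    expect_equal(curve$curve, o)
  }
})

test_that("EHH is monotone non-increasing away from the focal SNP", {
  sim <- small_sim(n_ind = 30, n_snps = 80, seed = 52)
  for (j in c(10, 40, 70)) {
    for (al in 0:1) {
      if (sum(sim$haps[, j] == al) < 2) next
      cv <- ehh(sim$haps, sim$loci, j, al, cutoff = 0)$curve
      fidx <- which(cv$ehh == 1)[1]
      expect_true(all(diff(cv$ehh[seq_len(fidx)]) >= 0))
      expect_true(all(diff(cv$ehh[fidx:nrow(cv)]) <= 0))
    }
  }
})

test_that("iHH integrates the trapezoid by hand examples", {
  two_point <- structure(list(curve = data.frame(
    pos = c(1, 1e6 + 1, 2e6 + 1), ehh = c(0, 1, 0))), class = "ehh_curve")
  expect_equal(ihh(two_point), 1e6)

  three_point <- structure(list(curve = data.frame(
    pos = c(0, 1e5, 2e5), ehh = c(1, 0.5, 0.05))), class = "ehh_curve")
  # one side only: 0.5*1e5*(1+0.5) + 0.5*1e5*(0.5+0.05)
  expect_equal(ihh(three_point), 102500)
})

test_that("identical areas on both alleles give zero unstandardized score", {
  scan <- data.frame(snp = sprintf("s%d", 1:4), chrom = "1",
                     pos = (1:4) * 1e6, freq1 = 0.5,
                     ihh0 = c(2e5, 1e5, 3e5, 2e5),
                     ihh1 = c(2e5, 3e5, 1e5, 1e5), ok = TRUE)
  res <- ihs_from_scan(scan, rep(1L, 4), min_bin = 1L)
  expect_equal(res$uihs[1], 0)
  expect_equal(res$uihs[2], log(3))
})

test_that("flipping the ancestral allele negates the unstandardized score", {
  sim <- small_sim(n_ind = 40, n_snps = 150, seed = 53)
  scan <- ihh_scan(sim$haps, sim$loci)
  anc <- assign_ancestral(sim$haps, "major")
  a <- ihs_from_scan(scan, anc)
  b <- ihs_from_scan(scan, ifelse(is.na(anc), NA_integer_, 1L - anc))
  expect_equal(a$uihs, -b$uihs)
})

test_that("a replicate whose assignment equals the major one reduces to it", {
  # the replicate path (precomputed areas + explicit assignment) must be the
  # same pure function of the assignment as the full major-mode scan
  sim <- small_sim(n_ind = 30, n_snps = 120, seed = 54)
  scan <- ihh_scan(sim$haps, sim$loci)
  major <- ihs_scan(sim$haps, sim$loci, mode = "major")
  forced <- ihs_from_scan(scan, assign_ancestral(sim$haps, "major"))
  expect_equal(forced$abs_ihs, major$abs_ihs)
  expect_equal(forced$ihs, major$ihs)
})

test_that("standardization yields per-bin mean 0 and SD 1", {
  expect_equal(standardize_ihs(c(1, 2, 3), rep(0.3, 3), min_bin = 1)$z,
               c(-1, 0, 1))
  set.seed(55)
  u <- stats::rnorm(500)
  f <- stats::runif(500)
  st <- standardize_ihs(u, f)
  for (b in unique(st$bin)) {
    expect_lt(abs(mean(st$z[st$bin == b])), 1e-9)
    expect_lt(abs(stats::sd(st$z[st$bin == b]) - 1), 1e-9)
  }
  # sparse bins are merged up to the minimum occupancy
  expect_true(all(table(st$bin) >= 10))
})

test_that("extreme calling is strict and recountable", {
  ihs <- c(3.2, -4.0, 3.2000001, NA, 0.5)
  flag <- call_extreme(ihs)
  expect_equal(flag, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  sim <- small_sim(n_ind = 50, n_snps = 300, seed = 56)
  res <- ihs_scan(sim$haps, sim$loci)
  expect_equal(sum(res$extreme),
               sum(abs(res$ihs) > 3.2, na.rm = TRUE))
})

test_that("sub-threshold MAF SNPs never receive an iHS value", {
  sim <- small_sim(n_ind = 40, n_snps = 200, maf_floor = 0, seed = 57)
  res <- ihs_scan(sim$haps, sim$loci)
  freq <- colMeans(sim$haps)
  low <- pmin(freq, 1 - freq) < 0.05
  expect_true(any(low))
  expect_true(all(is.na(res$ihs[low])))
})

test_that("random replicates agree with the major mode on clean data", {
  sim <- small_sim(n_ind = 50, n_snps = 250, seed = 58)
  rr <- run_random_replicates(sim$haps, sim$loci, n_reps = 10, seed = 3)
  expect_gt(rr$rank_cor, 0.9)
  expect_true(all(rr$per_snp$n_scored[!is.na(rr$per_snp$mean_abs_ihs)] > 0))
})
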
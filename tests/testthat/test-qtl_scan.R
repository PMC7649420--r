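# A compact synthetic design reused across scan tests
scan_fixture <- function(seed = 17, n = 98, n_bins = 40, n_chrom = 2) {
  set.seed(seed)
  per <- n_bins / n_chrom
  geno <- matrix(sample(c("P1", "HET", "P2"), n * n_bins, replace = TRUE,
                        prob = c(.25, .5, .25)), n, n_bins)
  colnames(geno) <- paste0("bin", seq_len(n_bins))
  list(geno = geno, enc = encode_genotypes(geno),
       bin_chrom = rep(paste0("chr", seq_len(n_chrom)), each = per))
}

test_that("genotype encoding follows the F2 coding", {
  g <- matrix(c("P1", "HET", "P2"), 3, 1)
  enc <- encode_genotypes(g)
  expect_equal(enc$xa[, 1], c(-1, 0, 1))
  expect_equal(enc$xd[, 1], c(0, 1, 0))
  expect_equal(sum(enc$xd), sum(g == "HET"))
})

test_that("LOD equals the brute-force nested-OLS oracle", {
  fx <- scan_fixture()
  set.seed(23)
  for (rep in 1:5) {
    y <- rnorm(98)
    cof <- select_cofactors(y, fx$enc$xa, 3)
    prof <- scan_trait(y, fx$enc$xa, fx$enc$xd, fx$bin_chrom, cof)
    expect_equal(prof$lod,
                 oracle_lod(y, fx$enc$xa, fx$enc$xd, fx$bin_chrom, cof),
                 tolerance = 1e-8)
  }
  # and with no cofactors
  y <- rnorm(98)
  prof0 <- scan_trait(y, fx$enc$xa, fx$enc$xd, fx$bin_chrom)
  expect_equal(prof0$lod, oracle_lod(y, fx$enc$xa, fx$enc$xd, fx$bin_chrom),
               tolerance = 1e-8)
})

test_that("scan is scale/shift invariant and permutation equivariant", {
  fx <- scan_fixture()
  set.seed(29)
  y <- rnorm(98) + fx$enc$xa[, 7]
  p1 <- scan_trait(y, fx$enc$xa, fx$enc$xd, fx$bin_chrom)
  p2 <- scan_trait(3.7 * y - 11, fx$enc$xa, fx$enc$xd, fx$bin_chrom)
  expect_equal(p1$lod, p2$lod, tolerance = 1e-9)
  perm <- sample(98)
  p3 <- scan_trait(y[perm], fx$enc$xa[perm, ], fx$enc$xd[perm, ],
                   fx$bin_chrom)
  expect_equal(p1$lod, p3$lod, tolerance = 1e-9)
})

test_that("degenerate traits and perfect fits are handled", {
  fx <- scan_fixture()
  expect_warning(p <- scan_trait(rep(1, 98), fx$enc$xa, fx$enc$xd,
                                 fx$bin_chrom), "zero-variance")
  expect_true(all(p$lod == 0))
  # noiseless single-bin trait: capped LOD at the causal bin
  y <- fx$enc$xa[, 5]
  p2 <- scan_trait(y, fx$enc$xa, fx$enc$xd, fx$bin_chrom)
  expect_equal(p2$lod[5], 300)
  # all-HET bin: additive column constant, dominance too -> LOD 0 there
  g <- fx$geno; g[, 3] <- "HET"
  enc <- encode_genotypes(g)
  set.seed(1); y3 <- rnorm(98)
  p3 <- scan_trait(y3, enc$xa, enc$xd, fx$bin_chrom)
  expect_equal(p3$lod[3], 0)
})

test_that("a large planted effect is the first cofactor", {
  fx <- scan_fixture()
  set.seed(37)
  y <- 2 * fx$enc$xa[, 12] + rnorm(98, sd = 0.5)
  cof <- select_cofactors(y, fx$enc$xa, 3)
  expect_equal(cof[1], 12)
  expect_length(select_cofactors(y, fx$enc$xa, 0), 0)
})

test_that("QTL calling respects threshold, support and merging", {
  bin_chrom <- rep("chr1", 20)
  expect_equal(nrow(call_qtls(rep(0, 20), bin_chrom)), 0)
  lod <- c(rep(0, 5), 2, 4, 6.7, 8, 6.9, 5.5, 1, rep(0, 8))
  calls <- call_qtls(lod, bin_chrom, lod_threshold = 5, lod_drop = 1.5)
  expect_equal(nrow(calls), 1)           # shoulders are not local maxima
  expect_equal(calls$peak_bin, 9)
  expect_equal(calls$support_start, 8)   # bins with LOD >= 6.5
  expect_equal(calls$support_end, 10)
  # boundary: LOD exactly 5 is called
  calls5 <- call_qtls(c(rep(0, 10), 5, rep(0, 9)), bin_chrom)
  expect_equal(calls5$peak_bin, 11)
  # two chromosomes, two planted QTLs
  fx <- scan_fixture()
  set.seed(41)
  y <- fx$enc$xa[, 8] + fx$enc$xa[, 30] + rnorm(98, sd = 0.9)
  cof <- select_cofactors(y, fx$enc$xa, 3)
  prof <- scan_trait(y, fx$enc$xa, fx$enc$xd, fx$bin_chrom, cof)
  calls2 <- call_qtls(prof, fx$bin_chrom)
  peaks <- calls2$peak_bin
  expect_true(any(abs(peaks - 8) <= 2))
  expect_true(any(abs(peaks - 30) <= 2))
})

test_that("permutation thresholds are deterministic and monotone in alpha", {
  fx <- scan_fixture()
  set.seed(43)
  y <- rnorm(98)
  t1 <- permutation_threshold(y, fx$enc$xa, fx$enc$xd, fx$bin_chrom,
                              n_perm = 120, alpha = 0.05, seed = 5)
  t2 <- permutation_threshold(y, fx$enc$xa, fx$enc$xd, fx$bin_chrom,
                              n_perm = 120, alpha = 0.05, seed = 5)
  expect_identical(t1$threshold, t2$threshold)
  t10 <- quantile(t1$max_lods, 0.90, type = 1)
  expect_lte(as.numeric(t10), t1$threshold)
  # vectorized permutation scan agrees with the per-trait scan
  Y <- cbind(y, rev(y))
  ml <- srnaqtl:::scan_max_lod(Y, fx$enc$xa, fx$enc$xd, fx$bin_chrom)
  expect_equal(ml[1],
               max(scan_trait(y, fx$enc$xa, fx$enc$xd, fx$bin_chrom)$lod),
               tolerance = 1e-9)
  expect_equal(ml[2],
               max(scan_trait(rev(y), fx$enc$xa, fx$enc$xd,
                              fx$bin_chrom)$lod),
               tolerance = 1e-9)
})

test_that("hotspot detection flags concentration, not uniform placement", {
  bin_chrom <- rep(c("chr1", "chr2"), each = 100)
  # concentrated: 200 traits at bin 57
  hs <- detect_hotspots(rep(57L, 200), 200, bin_chrom)
  expect_equal(nrow(hs), 1)
  expect_true(hs$bin_start <= 57 & hs$bin_end >= 57)
  expect_equal(hs$n_traits, 200)
  expect_equal(nrow(detect_hotspots(integer(0), 200, bin_chrom)), 0)
  # consecutive qualifying bins are one run
  hs2 <- detect_hotspots(rep(c(57L, 58L), c(100, 100)), 200, bin_chrom)
  expect_equal(nrow(hs2), 1)
  expect_equal(hs2$bin_end - hs2$bin_start, 1)
})

test_that("uniform null placement rarely produces hotspots", {
  bin_chrom <- rep(c("chr1", "chr2"), each = 100)
  set.seed(47)
  n_hot <- vapply(1:20, function(i) {
    peaks <- sample(200, 1000, replace = TRUE)
    nrow(detect_hotspots(peaks, 200, bin_chrom))
  }, numeric(1))
  expect_gte(mean(n_hot == 0), 0.95)
})
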
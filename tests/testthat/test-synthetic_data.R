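test_that("planted LIR structures appear at manifest coordinates", {
  d <- small_design()
  g <- simulate_parental_genomes(d)
  man <- g$manifest
  # parent2-only LIR: arm + spacer + revcomp(arm) in P2; P1 keeps arm1 only
  a1 <- man[man$feature == "lirA_arm1" & man$parent == "P2", ]
  a2 <- man[man$feature == "lirA_arm2" & man$parent == "P2", ]
  p2 <- g$genomes$P2[[a1$chrom]]
  arm1 <- substring(p2, a1$start, a1$end)
  arm2 <- substring(p2, a2$start, a2$end)
  expect_identical(arm2, revcomp(arm1))
  expect_false(any(man$feature == "lirA_arm2" & man$parent == "P1"))
  # spacer-length contrast: both parents carry both arms, lengths differ
  spec_b <- g$lir_specs[[2]]
  sp1 <- man[man$feature == "lirB_spacer" & man$parent == "P1", ]
  sp2 <- man[man$feature == "lirB_spacer" & man$parent == "P2", ]
  expect_equal(sp1$end - sp1$start + 1L, spec_b$spacer_p1)
  expect_equal(sp2$end - sp2$start + 1L, spec_b$spacer_p2)
  b1 <- man[man$feature == "lirB_arm1" & man$parent == "P1", ]
  b2 <- man[man$feature == "lirB_arm2" & man$parent == "P1", ]
  expect_identical(substring(g$genomes$P1[[b1$chrom]], b2$start, b2$end),
                   revcomp(substring(g$genomes$P1[[b1$chrom]], b1$start,
                                     b1$end)))
  # all manifest coordinates within their chromosome
  expect_true(all(man$start >= 1 & man$end <= d$chrom_len))
})

test_that("genome simulation is byte-identical across runs with one seed", {
  d <- small_design(5)
  g1 <- simulate_parental_genomes(d)
  g2 <- simulate_parental_genomes(d)
  expect_identical(g1$genomes, g2$genomes)
  expect_identical(g1$manifest, g2$manifest)
  dir1 <- tempfile(); dir2 <- tempfile()
  write_genome_fasta(g1, dir1); write_genome_fasta(g2, dir2)
  expect_identical(readLines(file.path(dir1, "P2.fa")),
                   readLines(file.path(dir2, "P2.fa")))
})

test_that("infeasible LIR placement fails naming the feature", {
  d <- small_design()
  bad <- list(lir_spec("too_far", "chr1", d$chrom_len - 100L))
  expect_error(simulate_parental_genomes(d, bad), "too_far")
})

test_that("IMF2 genotypes follow the paired-cross combination rule", {
  sc <- small_scenario()
  pop <- sc$pop
  expect_true(all(pop$ril_genotypes %in% c("P1", "P2")))
  for (i in sample(nrow(pop$cross_table), 5)) {
    g1 <- pop$ril_genotypes[pop$cross_table$ril1[i], ]
    g2 <- pop$ril_genotypes[pop$cross_table$ril2[i], ]
    gi <- pop$imf2_genotypes[i, ]
    expect_identical(unname(gi == "HET"), unname(g1 != g2))
    expect_identical(unname(gi[g1 == g2]), unname(g1[g1 == g2]))
  }
  # identical RILs crossed reproduce the RIL genotype with no HET
  bm_g <- pop$ril_genotypes[c(1, 1), ]
  ct <- data.frame(imf2 = "X", ril1 = rownames(pop$ril_genotypes)[1],
                   ril2 = rownames(pop$ril_genotypes)[1])
  bm <- build_bin_map(pop$ril_genotypes, pop$markers)
  dd <- deduce_imf2_genotypes(bm, ct)
  expect_identical(unname(dd[1, ]), unname(bm$ril_bin_genotypes[1, ]))
})

test_that("zero recombination yields whole-chromosome haplotypes", {
  d <- population_design(n_ril = 20, n_imf2 = 10, n_chrom = 2,
                         chrom_len = 50000L, markers_per_chrom = 15,
                         recomb_prob = 0, seed = 3)
  g <- simulate_parental_genomes(d, list())
  pop <- simulate_population(g, d)
  m <- d$markers_per_chrom
  for (r in seq_len(d$n_ril)) for (cc in seq_len(d$n_chrom)) {
    hap <- pop$ril_genotypes[r, ((cc - 1) * m + 1):(cc * m)]
    expect_length(unique(hap), 1)
  }
})

test_that("crossover counts match the binomial expectation", {
  d <- population_design(n_ril = 200, n_imf2 = 98, n_chrom = 1,
                         chrom_len = 100000L, markers_per_chrom = 20,
                         recomb_prob = 0.05, map_expansion = 2, seed = 9)
  g <- simulate_parental_genomes(d, list())
  pop <- simulate_population(g, d)
  co <- apply(pop$ril_genotypes, 1, function(h) sum(h[-1] != h[-length(h)]))
  p <- min(0.5, d$recomb_prob * d$map_expansion)
  expected <- 19 * p
  se <- sqrt(19 * p * (1 - p) / d$n_ril)
  expect_lt(abs(mean(co) - expected), 3 * se)
})

test_that("sRNA counts are NB-calibrated and conserve library totals", {
  sc <- small_scenario()
  d <- sc$genomes$design
  # depth-free replicate for marginal calibration
  sr <- simulate_srna_libraries(sc$genomes, sc$pop$imf2_genotypes, sc$truth,
                                d, dispersion = 0.1, depth_range = c(1, 1),
                                background_tags = 10)
  neutral <- sc$truth$tags$tag[sc$truth$tags$set == "neutral"]
  mu <- sc$truth$expression_means[neutral[1], "P1"]
  x <- sr$trait_counts[neutral, ]
  n <- length(x)
  expect_lt(abs(mean(x) - mu), 3 * sqrt((mu + 0.1 * mu^2) / n))
  # conservation: reported total equals the sum of all tag counts
  expect_equal(unname(sr$totals[1]), sum(sr$libraries[[1]]))
  # zero-mean cis tags are exactly 0 in non-expressing homozygotes
  cisA <- sc$truth$tags[sc$truth$tags$set == "cis_lirA", ]
  p1_ind <- sc$pop$imf2_genotypes[, paste0("m", cisA$ctrl_marker[1])] == "P1"
  expect_true(all(sr$trait_counts[cisA$tag, p1_ind] == 0))
})

test_that("trans effect scales group means by the configured fold", {
  d <- population_design(n_ril = 200, n_imf2 = 98, seed = 21)
  g <- simulate_parental_genomes(d)
  pop <- simulate_population(g, d)
  tr <- make_truth_table(g, pop, d, n_trans = 60, trans_fold = 3)
  sr <- simulate_srna_libraries(g, pop$imf2_genotypes, tr, d,
                                depth_range = c(1, 1), background_tags = 0)
  bio <- paste0("m", tr$biogenesis_marker)
  grp <- pop$imf2_genotypes[, bio]
  tt <- tr$tags$tag[tr$tags$set == "trans_bio"]
  m_p1 <- mean(sr$trait_counts[tt, grp == "P1"])
  m_p2 <- mean(sr$trait_counts[tt, grp == "P2"])
  expect_gt(sum(grp == "P1"), 15)
  expect_gt(sum(grp == "P2"), 15)
  expect_lt(abs(m_p2 / m_p1 - 3), 0.5)
})

test_that("mRNA reads are genotype-appropriate exact genome substrings", {
  sc <- small_scenario()
  mr <- sc$mrna
  # deletion genotype (P1 at lirA) contributes no lirA-locus reads: every
  # read of such an individual must come from decoys or other loci; all
  # reads must be exact substrings of one of the parent genomes
  p1g <- paste(unlist(sc$genomes$genomes$P1), collapse = "NNN")
  p2g <- paste(unlist(sc$genomes$genomes$P2), collapse = "NNN")
  ind <- sample(names(mr$libraries), 3)
  for (i in ind) {
    rd <- mr$libraries[[i]]$reads
    hit <- vapply(rd, function(r)
      grepl(r, p1g, fixed = TRUE) || grepl(r, p2g, fixed = TRUE), logical(1))
    expect_true(all(hit))
  }
  # expected RPM of a P1-genotype individual at the parent2-only LIR is 0
  gA <- sc$truth$lir_genotypes[, "lirA"]
  expect_true(all(mr$expected_rpm["lirA", gA == "P1"] == 0))
})

test_that("library depth scales aligned mRNA read counts proportionally", {
  sc <- small_scenario()
  d <- sc$genomes$design
  m1 <- simulate_mrna_libraries(sc$genomes, sc$pop$imf2_genotypes, sc$truth,
                                d, total_reads = 2e5, depth_range = c(1, 1),
                                n_decoy = 0)
  m2 <- simulate_mrna_libraries(sc$genomes, sc$pop$imf2_genotypes, sc$truth,
                                d, total_reads = 4e5, depth_range = c(1, 1),
                                n_decoy = 0)
  n1 <- mean(vapply(m1$libraries, function(l) length(l$reads), numeric(1)))
  n2 <- mean(vapply(m2$libraries, function(l) length(l$reads), numeric(1)))
  expect_lt(abs(n2 / n1 - 2), 0.25)
})
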
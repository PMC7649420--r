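test_that("constructed LIR is recovered at exact coordinates", {
  set.seed(71)
  arm <- rnd_dna(300); sp <- rnd_dna(50)
  left <- rnd_dna(400); right <- rnd_dna(300)
  s <- paste0(left, arm, sp, revcomp(arm), right)
  # force mismatching boundary pairs so the maximal arm is exactly as planted
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  fix_boundary <- function(s, p, q) {
    # make position p NOT pair with position q
    if (substring(s, p, p) == comp[substring(s, q, q)])
      substring(s, p, p) <- setdiff(c("A", "C"),
                                    comp[substring(s, q, q)])[1]
    s
  }
  s <- fix_boundary(s, 400, 1051)
  s <- fix_boundary(s, 701, 750)
  r <- find_inverted_repeats(s)
  expect_equal(nrow(r), 1)
  expect_equal(r$arm1_start, 401)
  expect_equal(r$arm1_end, 700)
  expect_equal(r$spacer_start, 701)
  expect_equal(r$spacer_end, 750)
  expect_equal(r$arm2_start, 751)
  expect_equal(r$arm2_end, 1050)
  expect_equal(r$identity, 1.0)
  expect_true(r$hairpin_competent)
})

test_that("random sequence contains no long inverted repeats", {
  set.seed(73)
  expect_equal(nrow(find_inverted_repeats(rnd_dna(10000), min_arm = 200)), 0)
})

test_that("finder equals the exhaustive substring-pair oracle on small input", {
  set.seed(79)
  for (rep in 1:5) {
    arm_len <- sample(40:80, 1)
    arm1 <- rnd_dna(arm_len)
    arm2 <- rnd_dna(sample(40:70, 1))
    s <- paste0(rnd_dna(200), arm1, rnd_dna(sample(c(30, 400), 1)),
                revcomp(arm1), rnd_dna(150), arm2, rnd_dna(60),
                revcomp(arm2), rnd_dna(200))
    got <- find_inverted_repeats(s, min_arm = 30, max_spacer = 2000,
                                 min_identity = 1, seed_k = 12)
    want <- oracle_inverted_repeats(s, min_arm = 30, max_spacer = 2000)
    # apply the documented longest-per-locus rule to the oracle set
    want <- want[order(-want$arm_len), , drop = FALSE]
    keep <- rep(TRUE, nrow(want))
    if (nrow(want) > 1) for (i in seq_len(nrow(want) - 1)) {
      if (!keep[i]) next
      for (j in (i + 1):nrow(want)) {
        ov1 <- want$arm1_start[j] <= want$arm1_end[i] &
          want$arm1_end[j] >= want$arm1_start[i]
        ov2 <- want$arm2_start[j] <= want$arm2_end[i] &
          want$arm2_end[j] >= want$arm2_start[i]
        if (ov1 && ov2) keep[j] <- FALSE
      }
    }
    want <- want[keep, ]
    key <- function(d) sort(paste(d$arm1_start, d$arm1_end,
                                  d$arm2_start, d$arm2_end))
    expect_identical(key(got), key(want))
  }
})

test_that("reverse-complementing the sequence mirrors record coordinates", {
  set.seed(83)
  arm <- rnd_dna(120)
  s <- paste0(rnd_dna(150), arm, rnd_dna(90), revcomp(arm), rnd_dna(100))
  f <- find_inverted_repeats(s, min_arm = 50, max_spacer = 1000)
  r <- find_inverted_repeats(revcomp(s), min_arm = 50, max_spacer = 1000)
  n <- nchar(s)
  expect_equal(nrow(f), nrow(r))
  expect_setequal(paste(n - r$arm2_end + 1, n - r$arm2_start + 1,
                        n - r$arm1_end + 1, n - r$arm1_start + 1),
                  paste(f$arm1_start, f$arm1_end, f$arm2_start, f$arm2_end))
})

test_that("spacer length drives hairpin competence and structural classes", {
  sc <- small_scenario()
  cfg <- run_config(seed = sc$genomes$design$seed)
  l1 <- find_inverted_repeats(unlist(sc$genomes$genomes$P1), min_arm = 200,
                              max_spacer = 20000)
  l2 <- find_inverted_repeats(unlist(sc$genomes$genomes$P2), min_arm = 200,
                              max_spacer = 20000)
  man <- sc$genomes$manifest
  loci <- do.call(rbind, lapply(c("lirA", "lirB", "lirC"), function(nm) {
    m <- man[man$feature == nm, ]
    data.frame(name = nm, chrom = m$chrom[1], start = min(m$start) - 500,
               end = max(m$end) + 500)
  }))
  cls <- suppressWarnings(
    compare_lir_across_genomes(l1, l2, loci, sc$genomes))
  expect_equal(cls$class[cls$locus == "lirA"], "one-hairpin")
  expect_equal(cls$hairpin_parent[cls$locus == "lirA"], "P2")
  expect_equal(cls$other_structure[cls$locus == "lirA"], "arm-only")
  expect_equal(cls$class[cls$locus == "lirB"], "one-hairpin")
  expect_equal(cls$hairpin_parent[cls$locus == "lirB"], "P2")
  expect_equal(cls$other_structure[cls$locus == "lirB"], "long-spacer")
  expect_equal(cls$class[cls$locus == "lirC"], "both-hairpin")
})

test_that("LIR expression quantification follows the RPM formula", {
  ref <- rnd_dna(500, seed = 89)
  reads <- substring(ref, seq(1, 350, 7), seq(1, 350, 7) + 99)
  libs <- list(
    i1 = list(reads = reads, total = 2e6),
    i2 = list(reads = c(reads[1:10], vapply(1:5, function(i)
      rnd_dna(100), character(1))), total = 1e6),
    i3 = list(reads = character(0), total = 1e6))
  vals <- quantify_lir_expression(libs, list(P1 = ref, P2 = NULL),
                                  c(i1 = "P1", i2 = "HET", i3 = "P1"))
  expect_equal(unname(vals["i1"]), length(reads) / 2)
  expect_equal(unname(vals["i2"]), 10)
  expect_equal(unname(vals["i3"]), 0)
  # deletion genotype: no reference -> 0
  vals2 <- quantify_lir_expression(libs[1], list(P1 = NULL, P2 = ref),
                                   c(i1 = "P1"))
  expect_equal(unname(vals2), 0)
  # zero-total individual excluded with a warning
  expect_warning(
    v3 <- quantify_lir_expression(list(z = list(reads = reads, total = 0)),
                                  list(P1 = ref, P2 = NULL), c(z = "P1")),
    "zero total")
  expect_true(is.na(v3))
})

test_that("simulated LIR expression recovers planted per-genotype levels", {
  sc <- small_scenario()
  truth <- sc$truth
  nm <- "lirA"
  li <- truth$lir_info[[nm]]
  sp <- li$spec
  g2 <- sc$genomes$genomes$P2[[sp$chrom]]
  cc2 <- srnaqtl:::lir_coords(sp, 2)
  refs <- list(P1 = NULL,
               P2 = substring(g2, cc2$arm1[1], cc2$arm2[2]))
  geno <- truth$lir_genotypes[, nm]
  vals <- quantify_lir_expression(sc$mrna$libraries, refs, geno)
  med <- tapply(vals, geno, median)
  planted <- truth$lir_expression[nm, ]
  expect_lt(abs(med[["P2"]] - planted[["P2"]]), 0.35 * planted[["P2"]])
  expect_equal(unname(med[["P1"]]), 0)
})

test_that("genotype association reproduces exact rank-sum results", {
  a <- associate_expression_genotype(c(1, 2, 3, 1, 2, 3),
                                     rep(c("P1", "P2"), each = 3))
  expect_equal(a$tests$p_value, 1)
  b <- associate_expression_genotype(c(1, 2, 3, 10, 11, 12),
                                     rep(c("P1", "P2"), each = 3))
  expect_equal(b$tests$p_value, 0.1)   # extreme 3-vs-3 two-sided exact p
  expect_equal(b$summary$median, c(2, 11))
  expect_error(associate_expression_genotype(1:3, rep("P1", 3)), "2 nonempty")
})

test_that("sRNA-LIR correlations hit the algebraic extremes and the null", {
  x <- c(1, 3, 2, 5, 4, 6, 8, 7)
  m <- rbind(prop = 2 * x + 1, anti = -x, flat = rep(2, 8))
  r <- correlate_srna_lir(m, x)
  expect_equal(unname(r["prop"]), 1)
  expect_equal(unname(r["anti"]), -1)
  expect_true(is.na(r["flat"]))
  set.seed(97)
  null_m <- matrix(rnorm(200 * 98), 200,
                   dimnames = list(paste0("t", 1:200), NULL))
  rr <- correlate_srna_lir(null_m, rnorm(98))
  crit <- qnorm(0.975) / sqrt(98 - 3)          # Fisher-z null cutoff
  frac <- mean(abs(rr) > crit)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("planted hairpin contrast shows genotype-dependent sRNA medians", {
  sc <- small_scenario()
  tg <- collapse_reads(sc$srna$libraries)
  rpm <- rpm_normalize(tg)
  cisA <- sc$truth$tags$tag[sc$truth$tags$set == "cis_lirA"]
  cisA <- intersect(cisA, rownames(rpm))
  geno <- sc$truth$lir_genotypes[, "lirA"]
  mean_expr <- colMeans(rpm[cisA, , drop = FALSE])
  med <- tapply(mean_expr, geno, median)
  expect_gt(med[["P2"]], 0)
  expect_equal(unname(med[["P1"]]), 0)
})
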
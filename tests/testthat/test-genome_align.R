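test_that("tag alignment equals the naive Hamming oracle", {
  set.seed(53)
  chrom <- rnd_dna(3000)
  genome <- c(chr1 = chrom)
  tags <- c(substring(chrom, 101, 121),              # planted forward
            revcomp(substring(chrom, 501, 524)),     # planted minus strand
            vapply(1:30, function(i) rnd_dna(22), character(1)))
  names(tags) <- paste0("t", seq_along(tags))
  for (mm in 0:1) {
    hits <- align_tags(tags, genome, max_mismatch = mm)
    for (i in seq_along(tags)) {
      got <- hits[hits$query == names(tags)[i],
                  c("start", "end", "strand", "mismatches")]
      got <- got[order(got$start, got$strand), ]
      want <- oracle_align(tags[i], chrom, mm)
      want <- want[order(want$start, want$strand), ]
      expect_equal(unname(as.matrix(got[, c("start", "end", "mismatches")])),
                   unname(as.matrix(want[, c("start", "end", "mismatches")])),
                   ignore_attr = TRUE)
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("parent-specific tags hit only the carrying genome", {
  sc <- small_scenario()
  man <- sc$genomes$manifest
  a2 <- man[man$feature == "lirA_arm2" & man$parent == "P2", ]
  tag <- substring(sc$genomes$genomes$P2[[a2$chrom]], a2$start, a2$start + 23)
  hits <- align_tags(c(q = tag), sc$genomes)
  expect_true(any(hits$genome == "P2"))
  # arm2 is absent from P1 but is the reverse complement of arm1, so any P1
  # hit must be on the minus strand at arm1
  p1 <- hits[hits$genome == "P1", ]
  expect_true(all(p1$strand == "-"))
})

test_that("unique mode reports only single-hit tags", {
  chrom <- rnd_dna(2000, seed = 59)
  dup <- substring(chrom, 301, 322)
  genome <- c(chr1 = paste0(chrom, dup))   # duplicated site
  uni <- substring(chrom, 901, 922)
  hits <- align_tags(c(a = dup, b = uni), genome, report = "unique")
  expect_false("a" %in% hits$query)
  expect_equal(sum(hits$query == "b"), 1)
})

test_that("cluster alignment relocates simulated clusters to their source", {
  sc <- small_scenario()
  g2 <- sc$genomes$genomes$P2
  frag <- substring(g2$chr2, 5001, 5151)   # unique single-copy interval
  hits <- align_clusters(c(cl = frag), g2)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$identity, 1.0)
  expect_equal(hits$coverage, 1.0)
  expect_lte(abs(hits$start - 5001), 5)
  # a two-copy repeat is dropped in unique mode
  rep2 <- list(chrX = paste0(frag, rnd_dna(200, 61), frag))
  expect_equal(nrow(align_clusters(c(cl = frag), rep2)), 0)
  expect_equal(nrow(align_clusters(c(cl = frag), rep2,
                                   unique_only = FALSE)), 2)
})

test_that("local/distant resolution follows the distance rule", {
  bins <- data.frame(bin = 1:4, chrom = c("chr1", "chr1", "chr2", "chr2"),
                     start = c(1, 50001, 1, 50001),
                     end = c(50000, 100000, 50000, 100000),
                     first_marker = 1:4, last_marker = 1:4, n_markers = 1)
  bm <- structure(list(bins = bins), class = "bin_map")
  qtls <- data.frame(trait = c("a", "b", "c"), chrom = "chr1",
                     peak_bin = 1, lod = 10,
                     support_start = 1, support_end = 1)
  hits <- data.frame(query = c("a", "b"),
                     chrom = c("chr1", "chr2"),
                     start = c(10000, 10000), end = c(10021, 10021),
                     strand = "+", mismatches = 0)
  out <- resolve_local_distant(qtls, hits, bm, max_dist = 1e6)
  expect_equal(out$mode, c("local", "distant", "unresolved"))
  # distance window matters: same chromosome but out of range
  hits2 <- data.frame(query = "a", chrom = "chr1", start = 90000,
                      end = 90021, strand = "+", mismatches = 0)
  out2 <- resolve_local_distant(qtls[1, ], hits2, bm, max_dist = 10000)
  expect_equal(out2$mode, "distant")
})

test_that("planted cis traits resolve local, trans distant, end to end", {
  sc <- small_scenario()
  tg <- collapse_reads(sc$srna$libraries)
  rpm <- rpm_normalize(tg)
  st <- define_s_traits(rpm, tg$counts)
  bm <- build_bin_map(sc$pop$ril_genotypes, sc$pop$markers,
                      chrom_len = sc$genomes$design$chrom_len)
  ib <- deduce_imf2_genotypes(bm, sc$pop$cross_table)
  calls <- scan_traits(st$values, ib, bm$bins$chrom, k = 3)
  hits <- align_tags(setNames(unique(calls$trait), unique(calls$trait)),
                     sc$genomes)
  calls <- resolve_local_distant(calls, hits, bm)
  # calls at the planted bins must carry the planted regulation mode
  truth <- sc$truth
  bin_of <- function(mk) bm$bins$bin[bm$bins$first_marker <= mk &
                                       bm$bins$last_marker >= mk][1]
  modes <- lapply(seq_len(nrow(truth$planted_qtls)), function(i) {
    q <- truth$planted_qtls[i, ]
    tg2 <- truth$tags$tag[truth$tags$set == q$set]
    near <- calls[calls$trait %in% tg2 &
                    abs(calls$peak_bin - bin_of(q$ctrl_marker)) <= 2, ]
    list(mode = q$mode, got = near$mode)
  })
  for (m in modes) {
    expect_gt(length(m$got), 10)
    expect_true(all(m$got == m$mode))
  }
})

test_that("authentication keeps hits near local QTLs only", {
  bins <- data.frame(bin = 1:2, chrom = c("chr1", "chr2"),
                     start = c(1, 1), end = c(100000, 100000),
                     first_marker = 1:2, last_marker = 1:2, n_markers = 1)
  bm <- structure(list(bins = bins), class = "bin_map")
  qtls <- data.frame(trait = "t", chrom = "chr1", peak_bin = 1, lod = 9,
                     support_start = 1, support_end = 1, mode = "local")
  hits <- data.frame(query = "t", genome = "P2",
                     chrom = c("chr1", "chr1", "chr2"),
                     start = c(5000, 20000, 5000),
                     end = c(5021, 20021, 5021),
                     strand = c("+", "-", "+"), mismatches = 0)
  # the two-arm pattern: both within-window hits retained
  auth <- authenticate_alignments(hits, qtls, bm, max_dist = 1e6)
  expect_equal(nrow(auth), 2)
  expect_true(all(auth$chrom == "chr1"))
  # no local QTL -> empty authentic set
  qtls_d <- transform(qtls, mode = "distant")
  expect_equal(nrow(authenticate_alignments(hits, qtls_d, bm)), 0)
  # hits far from every QTL -> empty
  far <- transform(hits, chrom = "chr2")
  expect_equal(nrow(authenticate_alignments(far, qtls, bm)), 0)
})

test_that("strand symmetry: reverse-complemented genome mirrors hits", {
  chrom <- rnd_dna(1500, seed = 67)
  tag <- substring(chrom, 701, 722)
  h_f <- align_tags(c(t = tag), c(chr1 = chrom))
  h_r <- align_tags(c(t = tag), c(chr1 = revcomp(chrom)))
  expect_equal(nrow(h_f), nrow(h_r))
  n <- nchar(chrom)
  expect_setequal(paste(n - h_r$end + 1, n - h_r$start + 1,
                        ifelse(h_r$strand == "+", "-", "+")),
                  paste(h_f$start, h_f$end, h_f$strand))
})
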
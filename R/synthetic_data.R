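# Synthetic biparental population generator: two parental genomes differing by
# planted SNPs and long-inverted-repeat (LIR) structure, recombinant inbred
# lines (RILs) bred to fixation, immortalized F2s (IMF2s) from paired crosses,
# and per-individual sRNA / mRNA libraries whose abundances carry planted cis
# (LIR genotype) and trans (biogenesis-locus genotype) effects.

#' Population design for the synthetic generator
#'
#' @param n_ril number of recombinant inbred lines.
#' @param n_imf2 number of immortalized F2 individuals (paired crosses of RILs).
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp (all chromosomes equal).
#' @param markers_per_chrom number of SNP markers per chromosome, evenly spaced.
#' @param recomb_prob meiotic crossover probability per marker interval.
#' @param map_expansion multiplier on `recomb_prob` approximating map expansion
#'   accumulated over the selfing generations of RIL construction.
#' @param seed integer seed; every downstream simulation derives its stream
#'   from it.
#' @return an object of class `population_design`.
#' @export
population_design <- function(n_ril = 200, n_imf2 = 98, n_chrom = 2,
                              chrom_len = 300000L, markers_per_chrom = 100,
                              recomb_prob = 0.05, map_expansion = 2,
                              seed = 1L) {
  d <- list(n_ril = as.integer(n_ril), n_imf2 = as.integer(n_imf2),
            n_chrom = as.integer(n_chrom), chrom_len = as.integer(chrom_len),
            markers_per_chrom = as.integer(markers_per_chrom),
            recomb_prob = recomb_prob, map_expansion = map_expansion,
            seed = as.integer(seed))
  if (d$n_imf2 > d$n_ril * (d$n_ril - 1) / 2)
    stop("n_imf2 exceeds the number of distinct RIL pairs")
  if (recomb_prob < 0 || recomb_prob > 1)
    stop("recomb_prob must be in [0,1]")
  class(d) <- "population_design"
  d
}

#' Marker positions implied by a design
#'
#' Markers are evenly spaced along each chromosome.
#'
#' @param design a `population_design`.
#' @return data.frame with columns marker (global index), chrom, pos.
#' @export
marker_positions <- function(design) {
  m <- design$markers_per_chrom
  per <- round(design$chrom_len * seq_len(m) / (m + 1))
  data.frame(
    marker = seq_len(design$n_chrom * m),
    chrom = rep(paste0("chr", seq_len(design$n_chrom)), each = m),
    pos = rep(per, design$n_chrom)
  )
}

#' Specification of one planted long inverted repeat
#'
#' A LIR is an arm, a spacer, and the reverse complement of the arm. Presence
#' per parent is "full" (both arms), "arm1" (first arm only, the arm-lost
#' configuration) or "none".
#'
#' @param name locus label.
#' @param chrom chromosome name.
#' @param start 1-based start of the structure in both parents.
#' @param arm_len arm length in bp.
#' @param spacer_p1,spacer_p2 spacer lengths per parent (ignored when the
#'   parent's presence is not "full").
#' @param presence_p1,presence_p2 one of "full", "arm1", "none".
#' @return a `lir_spec` list.
#' @export
lir_spec <- function(name, chrom, start, arm_len = 300,
                     spacer_p1 = 300, spacer_p2 = 300,
                     presence_p1 = "full", presence_p2 = "full") {
  stopifnot(presence_p1 %in% c("full", "arm1", "none"),
            presence_p2 %in% c("full", "arm1", "none"))
  structure(list(name = name, chrom = chrom, start = as.integer(start),
                 arm_len = as.integer(arm_len),
                 spacer_p1 = as.integer(spacer_p1),
                 spacer_p2 = as.integer(spacer_p2),
                 presence_p1 = presence_p1, presence_p2 = presence_p2),
            class = "lir_spec")
}

#' Default planted LIR loci
#'
#' Three configurations spanning the structural classes observed between
#' diverged parental genomes: a LIR present in parent 2 only (parent 1 retains
#' a single arm), a LIR whose spacer is short (hairpin-competent) in parent 2
#' but very long in parent 1, and a LIR intact with a short spacer in both.
#'
#' @param design a `population_design`.
#' @return list of `lir_spec`.
#' @export
default_lir_specs <- function(design) {
  list(
    lir_spec("lirA", "chr1", 40001L, arm_len = 300,
             spacer_p2 = 300, presence_p1 = "arm1", presence_p2 = "full"),
    lir_spec("lirB", "chr1", 80001L, arm_len = 300,
             spacer_p1 = 5000, spacer_p2 = 300),
    lir_spec("lirC", "chr1", 140001L, arm_len = 300,
             spacer_p1 = 300, spacer_p2 = 300)
  )
}

lir_window <- function(spec) {
  len <- 2L * spec$arm_len +
    max(if (spec$presence_p1 == "full") spec$spacer_p1 else 0L,
        if (spec$presence_p2 == "full") spec$spacer_p2 else 0L)
  c(spec$start, spec$start + len - 1L)
}

# coordinates of the structure actually present in one parent; NULL if "none"
lir_coords <- function(spec, parent) {
  pres <- if (parent == 1) spec$presence_p1 else spec$presence_p2
  sp <- if (parent == 1) spec$spacer_p1 else spec$spacer_p2
  a <- spec$arm_len
  s <- spec$start
  if (pres == "none") return(NULL)
  if (pres == "arm1")
    return(list(arm1 = c(s, s + a - 1L), arm2 = NULL, spacer = NULL,
                presence = "arm1"))
  list(arm1 = c(s, s + a - 1L),
       spacer = c(s + a, s + a + sp - 1L),
       arm2 = c(s + a + sp, s + 2L * a + sp - 1L),
       presence = "full")
}

#' Simulate the two parental genomes
#'
#' Both parents share a random background sequence per chromosome. SNPs are
#' substituted in parent 2 at every marker position that does not fall inside
#' a planted structural feature; LIR structures are written into reserved
#' windows by substitution so the two parents keep identical chromosome
#' lengths and a shared coordinate system.
#'
#' @param design a `population_design`.
#' @param lir_specs list of `lir_spec` (default `default_lir_specs(design)`).
#' @return a `genome_pair`: parent names, genomes (named character vectors of
#'   chromosome sequences), a feature manifest (1-based inclusive
#'   coordinates), marker table, and the LIR specs.
#' @export
simulate_parental_genomes <- function(design,
                                      lir_specs = default_lir_specs(design)) {
  markers <- marker_positions(design)
  chroms <- paste0("chr", seq_len(design$n_chrom))
  local_seed(design$seed, {
    base <- lapply(chroms, function(ch) random_dna(design$chrom_len))
    names(base) <- chroms

    # reserved windows: LIRs plus a shared trans-source region used for
    # trans-regulated sRNA tags and mRNA decoy reads
    windows <- lapply(lir_specs, function(sp) {
      w <- lir_window(sp)
      if (w[2] > design$chrom_len)
        stop("infeasible placement: LIR '", sp$name, "' exceeds chromosome")
      data.frame(name = sp$name, chrom = sp$chrom, start = w[1], end = w[2])
    })
    trans_src <- data.frame(name = "trans_source", chrom = "chr1",
                            start = design$chrom_len - 20000L,
                            end = design$chrom_len - 15001L)
    windows <- do.call(rbind, c(windows, list(trans_src)))
    for (ch in unique(windows$chrom)) {
      w <- windows[windows$chrom == ch, , drop = FALSE]
      w <- w[order(w$start), , drop = FALSE]
      if (nrow(w) > 1 && any(w$start[-1] <= w$end[-nrow(w)]))
        stop("infeasible placement: overlapping features on ", ch)
    }

    p1 <- base
    p2 <- base

    # SNPs in parent 2 at marker positions outside reserved windows
    snp_rows <- list()
    for (i in seq_len(nrow(markers))) {
      ch <- markers$chrom[i]; pos <- markers$pos[i]
      inwin <- any(windows$chrom == ch & windows$start <= pos &
                     windows$end >= pos)
      if (inwin) next
      ref <- substring(p1[[ch]], pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      substring(p2[[ch]], pos, pos) <- alt
      snp_rows[[length(snp_rows) + 1]] <-
        data.frame(feature = paste0("snp_m", markers$marker[i]), type = "snp",
                   parent = "both", chrom = ch, start = pos, end = pos,
                   note = paste0(ref, ">", alt))
    }

    # LIR structures
    manifest <- list()
    for (sp in lir_specs) {
      arm <- random_dna(sp$arm_len)
      for (parent in 1:2) {
        cc <- lir_coords(sp, parent)
        if (is.null(cc)) next
        g <- if (parent == 1) p1 else p2
        substring(g[[sp$chrom]], cc$arm1[1], cc$arm1[2]) <- arm
        if (cc$presence == "full") {
          substring(g[[sp$chrom]], cc$spacer[1], cc$spacer[2]) <-
            random_dna(cc$spacer[2] - cc$spacer[1] + 1L)
          substring(g[[sp$chrom]], cc$arm2[1], cc$arm2[2]) <- revcomp(arm)
        }
        if (parent == 1) p1 <- g else p2 <- g
        pn <- paste0("P", parent)
        manifest[[length(manifest) + 1]] <- data.frame(
          feature = sp$name, type = "lir", parent = pn, chrom = sp$chrom,
          start = cc$arm1[1],
          end = if (cc$presence == "full") cc$arm2[2] else cc$arm1[2],
          note = cc$presence)
        manifest[[length(manifest) + 1]] <- data.frame(
          feature = paste0(sp$name, "_arm1"), type = "lir_arm", parent = pn,
          chrom = sp$chrom, start = cc$arm1[1], end = cc$arm1[2], note = "")
        if (cc$presence == "full") {
          manifest[[length(manifest) + 1]] <- data.frame(
            feature = paste0(sp$name, "_spacer"), type = "lir_spacer",
            parent = pn, chrom = sp$chrom, start = cc$spacer[1],
            end = cc$spacer[2], note = "")
          manifest[[length(manifest) + 1]] <- data.frame(
            feature = paste0(sp$name, "_arm2"), type = "lir_arm", parent = pn,
            chrom = sp$chrom, start = cc$arm2[1], end = cc$arm2[2], note = "")
        }
      }
    }
    manifest[[length(manifest) + 1]] <-
      data.frame(feature = "trans_source", type = "region", parent = "both",
                 chrom = trans_src$chrom, start = trans_src$start,
                 end = trans_src$end, note = "")
    manifest <- rbind(do.call(rbind, manifest), do.call(rbind, snp_rows))
    structure(list(parent1_name = "P1", parent2_name = "P2",
                   genomes = list(P1 = p1, P2 = p2),
                   manifest = manifest, markers = markers,
                   lir_specs = lir_specs, design = design),
              class = "genome_pair")
  })
}

#' Write the two parental genomes as FASTA
#'
#' @param genomes a `genome_pair`.
#' @param dir output directory.
#' @return paths of the two FASTA files, invisibly.
#' @export
write_genome_fasta <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(c("P1", "P2"), function(p) {
    ss <- Biostrings::DNAStringSet(unlist(genomes$genomes[[p]]))
    f <- file.path(dir, paste0(p, ".fa"))
    Biostrings::writeXStringSet(ss, f)
    f
  }, character(1))
  invisible(paths)
}

#' Simulate RILs and IMF2s
#'
#' RILs are bred to fixation: a homozygous haplotype per chromosome with
#' crossovers between adjacent markers at probability
#' `recomb_prob * map_expansion`. IMF2s combine the haplotypes of two distinct
#' RILs per paired cross (each RIL used in one cross when enough RILs exist,
#' mirroring the paired-cross design); the IMF2 is heterozygous exactly where
#' the two crossed RILs differ.
#'
#' @param genomes a `genome_pair`.
#' @param design a `population_design`.
#' @return list with `ril_genotypes` (RILs x markers over {"P1","P2"}),
#'   `imf2_genotypes` (IMF2s x markers over {"P1","P2","HET"}),
#'   `cross_table` (imf2, ril1, ril2) and `markers`.
#' @export
simulate_population <- function(genomes, design) {
  markers <- genomes$markers
  m <- design$markers_per_chrom
  p_co <- min(0.5, design$recomb_prob * design$map_expansion)
  local_seed(design$seed + 1L, {
    ril <- matrix("", design$n_ril, nrow(markers))
    for (r in seq_len(design$n_ril)) {
      for (c in seq_len(design$n_chrom)) {
        a <- sample(c("P1", "P2"), 1)
        hap <- character(m)
        hap[1] <- a
        co <- runif(m - 1) < p_co
        for (j in 2:m) {
          if (co[j - 1]) a <- if (a == "P1") "P2" else "P1"
          hap[j] <- a
        }
        ril[r, ((c - 1) * m + 1):(c * m)] <- hap
      }
    }
    rownames(ril) <- paste0("RIL", seq_len(design$n_ril))
    colnames(ril) <- paste0("m", markers$marker)

    if (2L * design$n_imf2 <= design$n_ril) {
      picks <- sample(design$n_ril, 2L * design$n_imf2)
      pairs <- matrix(picks, ncol = 2)
    } else {
      all_pairs <- t(utils::combn(design$n_ril, 2))
      pairs <- all_pairs[sample(nrow(all_pairs), design$n_imf2), , drop = FALSE]
    }
    cross <- data.frame(imf2 = paste0("IMF2_", seq_len(design$n_imf2)),
                        ril1 = rownames(ril)[pairs[, 1]],
                        ril2 = rownames(ril)[pairs[, 2]])
    g1 <- ril[pairs[, 1], , drop = FALSE]
    g2 <- ril[pairs[, 2], , drop = FALSE]
    imf2 <- ifelse(g1 == g2, g1, "HET")
    rownames(imf2) <- cross$imf2
    list(ril_genotypes = ril, imf2_genotypes = imf2, cross_table = cross,
         markers = markers)
  })
}

marker_nearest <- function(markers, chrom, pos) {
  sub <- markers[markers$chrom == chrom, ]
  sub$marker[which.min(abs(sub$pos - pos))]
}

#' Build the truth table of planted expression effects
#'
#' Defines the simulated trait architecture: neutral tags expressed in every
#' individual, cis tag sets tiled from the arms of expressing LIR copies and
#' controlled by the genotype at the marker nearest the LIR, a trans tag set
#' tiled from a region shared by both parents but controlled by a designated
#' "biogenesis" marker on another chromosome, and per-genotype LIR mRNA
#' expression levels.
#'
#' @param genomes a `genome_pair`.
#' @param pop output of [simulate_population()].
#' @param design a `population_design`.
#' @param n_neutral,neutral_mean number and mean count of neutral tags.
#' @param n_cis tags per expressing LIR set.
#' @param cis_mean mean count under the expressing genotype.
#' @param cis_null_mean mean under the non-expressing genotype for loci where
#'   both parents carry the structure (lirB-style); exact 0 for presence /
#'   absence loci.
#' @param n_trans,trans_mean,trans_fold trans set size, baseline mean, and
#'   multiplicative effect of the P2 biogenesis genotype.
#' @param tag_sizes,tag_size_weights sRNA tag lengths and sampling weights.
#' @return a `truth_table` list: `tags` (metadata incl. controlling marker),
#'   `expression_means` (tags x {P1,HET,P2}), `planted_qtls`,
#'   `lir_genotypes` (IMF2 x LIR), `lir_expression` (RPM per genotype),
#'   `biogenesis_marker`.
#' @export
make_truth_table <- function(genomes, pop, design,
                             n_neutral = 300, neutral_mean = 50,
                             n_cis = 80, cis_mean = 60, cis_null_mean = 0.5,
                             n_trans = 150, trans_mean = 30, trans_fold = 3,
                             tag_sizes = c(21, 22, 23, 24),
                             tag_size_weights = c(.25, .25, .25, .25)) {
  markers <- genomes$markers
  local_seed(design$seed + 2L, {
    tile_tags <- function(seqsrc, n, sizes) {
      starts <- sample(nchar(seqsrc) - max(sizes), n, replace = TRUE)
      len <- if (length(sizes) == 1) rep(sizes, n) else
        sample(sizes, n, replace = TRUE,
               prob = tag_size_weights[match(sizes, tag_sizes)])
      unique(substring(seqsrc, starts, starts + len - 1))
    }
    tags <- list(); means <- list(); qtls <- list()
    add_set <- function(set, seqs, mu_p1, mu_het, mu_p2, marker, chrom, mode) {
      df <- data.frame(tag = seqs, set = set, size = nchar(seqs),
                       ctrl_marker = marker %||% NA_integer_,
                       stringsAsFactors = FALSE)
      tags[[length(tags) + 1]] <<- df
      means[[length(means) + 1]] <<-
        cbind(P1 = rep(mu_p1, nrow(df)), HET = rep(mu_het, nrow(df)),
              P2 = rep(mu_p2, nrow(df)))
      if (!is.null(marker))
        qtls[[length(qtls) + 1]] <<-
          data.frame(set = set, chrom = chrom, ctrl_marker = marker,
                     mode = mode, n_tags = nrow(df))
    }

    # neutral tags: random sequences, constant mean
    neutral <- unique(replicate(n_neutral, random_dna(
      sample(tag_sizes, 1, prob = tag_size_weights))))
    add_set("neutral", neutral, neutral_mean, neutral_mean, neutral_mean,
            NULL, NA, NA)

    # cis sets from expressing LIR copies
    lir_info <- list()
    for (sp in genomes$lir_specs) {
      cc1 <- lir_coords(sp, 1); cc2 <- lir_coords(sp, 2)
      hp <- function(cc, maxsp = 1000)
        !is.null(cc) && cc$presence == "full" &&
          (cc$spacer[2] - cc$spacer[1] + 1L) <= maxsp
      h1 <- hp(cc1); h2 <- hp(cc2)
      mk <- marker_nearest(markers, sp$chrom,
                           sp$start + sp$arm_len + sp$arm_len %/% 2)
      lir_info[[sp$name]] <- list(spec = sp, marker = mk, hp1 = h1, hp2 = h2)
      if (h1 == h2) next                      # no planted cis contrast
      expr_parent <- if (h2) 2 else 1
      cc <- if (expr_parent == 2) cc2 else cc1
      g <- genomes$genomes[[paste0("P", expr_parent)]][[sp$chrom]]
      # tile each arm separately: hairpin-derived sRNAs come from the stem,
      # and loop-junction-spanning tags would not exist in the genome
      seqs <- unique(c(
        tile_tags(substring(g, cc$arm1[1], cc$arm1[2]), ceiling(n_cis / 2),
                  tag_sizes),
        tile_tags(substring(g, cc$arm2[1], cc$arm2[2]), floor(n_cis / 2),
                  tag_sizes)))
      both_present <- !is.null(cc1) && !is.null(cc2) &&
        cc1$presence == "full" && cc2$presence == "full"
      null_mu <- if (both_present) cis_null_mean else 0
      mu_p1 <- if (expr_parent == 1) cis_mean else null_mu
      mu_p2 <- if (expr_parent == 2) cis_mean else null_mu
      add_set(paste0("cis_", sp$name), seqs, mu_p1, (mu_p1 + mu_p2) / 2,
              mu_p2, mk, sp$chrom, "local")
    }

    # trans set: 24-nt tags from the shared trans-source region, controlled by
    # a biogenesis marker in the middle of the last chromosome
    ts <- genomes$manifest[genomes$manifest$feature == "trans_source", ][1, ]
    # tile densely from a 1-kb window so the set assembles into clusters
    # expressed in every library
    src <- substring(genomes$genomes$P1[[ts$chrom]], ts$start,
                     min(ts$end, ts$start + 999L))
    bio_chrom <- paste0("chr", design$n_chrom)
    bio_marker <- marker_nearest(markers, bio_chrom, design$chrom_len %/% 2)
    seqs <- tile_tags(src, n_trans, 24)
    add_set("trans_bio", seqs, trans_mean, trans_mean * (1 + trans_fold) / 2,
            trans_mean * trans_fold, bio_marker, bio_chrom, "distant")

    tag_df <- do.call(rbind, tags)
    mean_mat <- do.call(rbind, means)
    rownames(mean_mat) <- tag_df$tag
    # drop accidental duplicate sequences across sets
    dup <- duplicated(tag_df$tag)
    tag_df <- tag_df[!dup, ]; mean_mat <- mean_mat[!dup, , drop = FALSE]

    lir_geno <- sapply(lir_info, function(li)
      pop$imf2_genotypes[, paste0("m", li$marker)])
    rownames(lir_geno) <- rownames(pop$imf2_genotypes)

    lir_expr <- rbind(
      lirA = c(P1 = 0, HET = 25, P2 = 50),
      lirB = c(P1 = 60, HET = 40, P2 = 25),
      lirC = c(P1 = 40, HET = 40, P2 = 40))
    lir_expr <- lir_expr[intersect(rownames(lir_expr), names(lir_info)), ,
                         drop = FALSE]

    structure(list(tags = tag_df, expression_means = mean_mat,
                   planted_qtls = do.call(rbind, qtls),
                   lir_genotypes = lir_geno, lir_info = lir_info,
                   lir_expression = lir_expr, biogenesis_marker = bio_marker,
                   trans_fold = trans_fold),
              class = "truth_table")
  })
}

#' Simulate per-IMF2 collapsed sRNA libraries
#'
#' Counts are negative-binomial around genotype-dependent means scaled by a
#' per-library depth factor; each library additionally receives private
#' low-count background tags reproducing the rare-tag skew of real sRNA data.
#'
#' @param genomes a `genome_pair`.
#' @param imf2_genotypes IMF2 x marker genotype matrix.
#' @param truth a `truth_table`.
#' @param design a `population_design`.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param depth_range library depth factors drawn uniformly from this range.
#' @param background_tags private background tags per library.
#' @param background_count_max background tag counts drawn from
#'   1..background_count_max.
#' @return list: `libraries` (per IMF2, named integer count vector),
#'   `trait_counts` (trait tags x IMF2 realized counts), `expected`
#'   (expected counts), `depth`, `totals`.
#' @export
simulate_srna_libraries <- function(genomes, imf2_genotypes, truth, design,
                                    dispersion = 0.1, depth_range = c(0.7, 1.3),
                                    background_tags = 500,
                                    background_count_max = 3) {
  n <- nrow(imf2_genotypes)
  tagd <- truth$tags
  local_seed(design$seed + 3L, {
    depth <- runif(n, depth_range[1], depth_range[2])
    # per-tag genotype column: controlling marker or NA (neutral)
    geno_of <- function(i) {
      g <- rep("P1", nrow(tagd))
      has <- !is.na(tagd$ctrl_marker)
      g[!has] <- "P1"                        # neutral: any column, means equal
      g[has] <- imf2_genotypes[i, paste0("m", tagd$ctrl_marker[has])]
      g
    }
    expected <- matrix(0, nrow(tagd), n,
                       dimnames = list(tagd$tag, rownames(imf2_genotypes)))
    counts <- expected
    for (i in seq_len(n)) {
      mu <- truth$expression_means[cbind(seq_len(nrow(tagd)), match(
        geno_of(i), colnames(truth$expression_means)))] * depth[i]
      expected[, i] <- mu
      counts[, i] <- rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    libraries <- lapply(seq_len(n), function(i) {
      ct <- counts[, i]
      ct <- ct[ct > 0]
      bg_len <- sample(c(18:30), background_tags, replace = TRUE)
      bg <- vapply(bg_len, random_dna, character(1))
      bg <- bg[!duplicated(bg) & !(bg %in% tagd$tag)]
      bgc <- sample(seq_len(background_count_max), length(bg), replace = TRUE)
      c(stats::setNames(as.integer(ct), names(ct)),
        stats::setNames(bgc, bg))
    })
    names(libraries) <- rownames(imf2_genotypes)
    list(libraries = libraries, trait_counts = counts, expected = expected,
         depth = depth, totals = vapply(libraries, sum, numeric(1)))
  })
}

#' Simulate per-IMF2 mRNA libraries over the LIR loci
#'
#' Reads are error-free substrings (default 100 bp) of the genotype-appropriate
#' parent's LIR locus; read numbers are Poisson around the planted per-genotype
#' expression level (reads per million) times library depth. Decoy reads from a
#' neutral genomic region are added so alignment specificity is exercised.
#'
#' @param genomes a `genome_pair`.
#' @param imf2_genotypes IMF2 x marker genotype matrix.
#' @param truth a `truth_table`.
#' @param design a `population_design`.
#' @param read_len read length.
#' @param total_reads nominal library size before the depth factor.
#' @param depth_range per-library depth factor range.
#' @param n_decoy decoy reads per library.
#' @return list: `libraries` (per IMF2: list(reads, total)), `expected_rpm`
#'   (LIR x IMF2 expected reads-per-million).
#' @export
simulate_mrna_libraries <- function(genomes, imf2_genotypes, truth, design,
                                    read_len = 100, total_reads = 1e6,
                                    depth_range = c(0.7, 1.3), n_decoy = 200) {
  n <- nrow(imf2_genotypes)
  lirs <- rownames(truth$lir_expression)
  # per-parent locus sequences
  locus_seq <- lapply(lirs, function(nm) {
    sp <- truth$lir_info[[nm]]$spec
    lapply(1:2, function(parent) {
      cc <- lir_coords(sp, parent)
      if (is.null(cc) || cc$presence != "full") return(NULL)
      g <- genomes$genomes[[paste0("P", parent)]][[sp$chrom]]
      substring(g, cc$arm1[1], cc$arm2[2])
    })
  })
  names(locus_seq) <- lirs
  decoy_src <- substring(genomes$genomes$P1$chr2, 1000, 11000)
  local_seed(design$seed + 4L, {
    depth <- runif(n, depth_range[1], depth_range[2])
    expected <- matrix(0, length(lirs), n,
                       dimnames = list(lirs, rownames(imf2_genotypes)))
    libraries <- lapply(seq_len(n), function(i) {
      tot <- round(total_reads * depth[i])
      reads <- character(0)
      for (nm in lirs) {
        g <- imf2_genotypes[i, paste0("m", truth$lir_info[[nm]]$marker)]
        rpm <- truth$lir_expression[nm, g]
        expected[nm, i] <<- rpm
        n_reads <- rpois(1, rpm * tot / 1e6)
        if (n_reads == 0) next
        srcs <- switch(g,
                       P1 = locus_seq[[nm]][1],
                       P2 = locus_seq[[nm]][2],
                       HET = locus_seq[[nm]])
        srcs <- Filter(Negate(is.null), srcs)
        if (length(srcs) == 0) next
        pick <- sample(length(srcs), n_reads, replace = TRUE)
        rd <- vapply(pick, function(k) {
          s <- srcs[[k]]
          st <- sample(nchar(s) - read_len + 1L, 1)
          substring(s, st, st + read_len - 1L)
        }, character(1))
        reads <- c(reads, rd)
      }
      if (n_decoy > 0) {
        dst <- sample(nchar(decoy_src) - read_len + 1L, n_decoy,
                      replace = TRUE)
        reads <- c(reads, substring(decoy_src, dst, dst + read_len - 1L))
      }
      list(reads = reads, total = tot)
    })
    names(libraries) <- rownames(imf2_genotypes)
    list(libraries = libraries, expected_rpm = expected, depth = depth)
  })
}
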
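# Long-inverted-repeat analysis: detect LIRs (arm + spacer + reverse
# complement of the arm), compare their structure across the two parents,
# quantify LIR expression from mRNA reads, and relate sRNA expression to LIR
# genotype and expression.

COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Find long inverted repeats in a sequence
#'
#' Seeds exact `seed_k`-mer matches between the sequence and its reverse
#' complement, merges co-antidiagonal seeds, extends each seed run outward
#' without gaps while arm identity stays at or above `min_identity`, filters
#' by arm length and spacer length, and keeps the longest-arm record per
#' locus (nested or arm-overlapping records are dropped).
#'
#' @param sequence a single DNA string, or a named character vector of
#'   chromosome sequences.
#' @param min_arm minimum arm length (bp).
#' @param max_spacer maximum spacer length (bp; spacer of at least 1 bp
#'   required so the two arms do not abut).
#' @param min_identity minimum arm identity (ungapped, matches / arm length).
#' @param seed_k exact seed length.
#' @param max_hairpin_spacer spacer length at or below which the record is
#'   flagged hairpin-competent.
#' @return data.frame: chrom, arm1_start, arm1_end, spacer_start, spacer_end,
#'   arm2_start, arm2_end, arm_len, spacer_len, identity, hairpin_competent;
#'   sorted by position.
#' @export
find_inverted_repeats <- function(sequence, min_arm = 200, max_spacer = 20000,
                                  min_identity = 0.9, seed_k = 15,
                                  max_hairpin_spacer = 1000) {
  if (length(sequence) > 1 || !is.null(names(sequence))) {
    nm <- names(sequence) %||% paste0("seq", seq_along(sequence))
    out <- lapply(seq_along(sequence), function(i) {
      r <- find_inverted_repeats(unname(sequence[i]), min_arm, max_spacer,
                                 min_identity, seed_k, max_hairpin_spacer)
      if (nrow(r)) r$chrom <- nm[i]
      r
    })
    out <- do.call(rbind, out)
    return(out[order(out$chrom, out$arm1_start), , drop = FALSE])
  }
  empty <- data.frame(chrom = character(0), arm1_start = integer(0),
                      arm1_end = integer(0), spacer_start = integer(0),
                      spacer_end = integer(0), arm2_start = integer(0),
                      arm2_end = integer(0), arm_len = integer(0),
                      spacer_len = integer(0), identity = numeric(0),
                      hairpin_competent = logical(0))
  n <- nchar(sequence)
  if (n < 2 * min_arm + 1) return(empty)
  v <- strsplit(sequence, "")[[1]]
  cv <- unname(COMP[v])

  np <- n - seed_k + 1L
  kmers <- substring(sequence, seq_len(np), seq_len(np) + seed_k - 1L)
  pos_env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(np)) pos_env[[kmers[i]]] <- c(pos_env[[kmers[i]]], i)
  rc_kmers <- revcomp(kmers)

  # seeds grouped by anti-diagonal c = i + j + k - 1 (position p on arm1
  # pairs with position c - p on arm2)
  seeds <- list()
  for (i in seq_len(np)) {
    js <- pos_env[[rc_kmers[i]]]
    js <- js[js > i]
    if (length(js))
      seeds[[length(seeds) + 1]] <-
        data.frame(i = i, c = i + js + seed_k - 1L)
  }
  if (length(seeds) == 0) return(empty)
  seeds <- do.call(rbind, seeds)

  pair_match <- function(p, c) v[p] == cv[c - p]
  recs <- list()
  for (cc in unique(seeds$c)) {
    is <- sort(seeds$i[seeds$c == cc])
    grp <- cumsum(c(TRUE, diff(is) > 1))
    for (g in unique(grp)) {
      i0 <- min(is[grp == g]); i1 <- max(is[grp == g]) + seed_k - 1L
      # X-drop extension (+1 match, -3 mismatch, drop 12). Every position
      # where the running score reaches a new maximum is a candidate stop
      # (candidates always end on a match); the final arm is the longest
      # left/right candidate combination whose identity stays above the
      # threshold, so clean flanks are never absorbed.
      xdrop_candidates <- function(from, step, limit) {
        cand_pos <- from - step; cand_mm <- 0L
        score <- 0; maxscore <- 0; mm <- 0L
        p <- from
        while (if (step > 0) p <= limit else p >= limit) {
          if (pair_match(p, cc)) score <- score + 1
          else { score <- score - 3; mm <- mm + 1L }
          if (score > maxscore) {
            maxscore <- score
            cand_pos <- c(cand_pos, p); cand_mm <- c(cand_mm, mm)
          }
          if (score < maxscore - 12) break
          p <- p + step
        }
        list(pos = cand_pos, mm = cand_mm)
      }
      lt <- xdrop_candidates(i0 - 1L, -1L, max(1L, cc - n))
      rt <- xdrop_candidates(i1 + 1L, 1L, floor((cc - 2) / 2))
      L <- i0; R <- i1; mmL <- 0L; mmR <- 0L; bestlen <- -1L
      for (a in seq_along(lt$pos)) for (b in seq_along(rt$pos)) {
        len_ab <- rt$pos[b] - lt$pos[a] + 1L
        mm_ab <- lt$mm[a] + rt$mm[b]
        if ((len_ab - mm_ab) / len_ab >= min_identity && len_ab > bestlen) {
          bestlen <- len_ab
          L <- lt$pos[a]; R <- rt$pos[b]; mmL <- lt$mm[a]; mmR <- rt$mm[b]
        }
      }
      len <- R - L + 1L
      sp <- cc - 2L * R - 1L
      ident <- (len - (mmL + mmR)) / len
      if (len >= min_arm && ident >= min_identity && sp >= 1 &&
            sp <= max_spacer)
        recs[[length(recs) + 1]] <-
          data.frame(arm1_start = L, arm1_end = R, arm2_start = cc - R,
                     arm2_end = cc - L, arm_len = len, spacer_len = sp,
                     identity = ident)
    }
  }
  if (length(recs) == 0) return(empty)
  recs <- unique(do.call(rbind, recs))
  # keep the longest-arm record per locus (cluster by arm1 overlap)
  recs <- recs[order(-recs$arm_len), , drop = FALSE]
  keep <- rep(TRUE, nrow(recs))
  for (i in seq_len(nrow(recs))) {
    if (!keep[i]) next
    if (i < nrow(recs)) for (j in (i + 1):nrow(recs)) {
      if (!keep[j]) next
      ov1 <- recs$arm1_start[j] <= recs$arm1_end[i] &
        recs$arm1_end[j] >= recs$arm1_start[i]
      ov2 <- recs$arm2_start[j] <= recs$arm2_end[i] &
        recs$arm2_end[j] >= recs$arm2_start[i]
      if (ov1 && ov2) keep[j] <- FALSE
    }
  }
  recs <- recs[keep, , drop = FALSE]
  recs$spacer_start <- recs$arm1_end + 1L
  recs$spacer_end <- recs$arm2_start - 1L
  recs$hairpin_competent <- recs$spacer_len <= max_hairpin_spacer
  recs$chrom <- NA_character_
  recs <- recs[order(recs$arm1_start), c(
    "chrom", "arm1_start", "arm1_end", "spacer_start", "spacer_end",
    "arm2_start", "arm2_end", "arm_len", "spacer_len", "identity",
    "hairpin_competent")]
  rownames(recs) <- NULL
  recs
}

#' Compare LIR structure between the two parental genomes
#'
#' For each matched locus (a window comparable across the parents), the
#' structural class is: "both-hairpin" when a hairpin-competent record exists
#' in both parents; "one-hairpin" when exactly one parent's copy is
#' hairpin-competent (the other being long-spacer, arm-lost or missing);
#' "arm-lost" when one parent only retains a single arm and neither copy is a
#' full IR elsewhere classified; "absent" when a locus has a record in
#' neither parent (or cannot be matched).
#'
#' @param lirs_p1,lirs_p2 record tables from [find_inverted_repeats()] run on
#'   each parent.
#' @param loci data.frame(name, chrom, start, end) homology map of windows.
#' @param genomes optional `genome_pair`; when given, the arm sequence of a
#'   one-sided record is searched in the other parent's window to separate
#'   "arm-lost" from full absence.
#' @return data.frame: locus, class, hairpin_parent, p1_spacer, p2_spacer.
#' @export
compare_lir_across_genomes <- function(lirs_p1, lirs_p2, loci,
                                       genomes = NULL) {
  in_window <- function(recs, w) {
    if (nrow(recs) == 0) return(recs)
    sel <- (is.na(recs$chrom) | recs$chrom == w$chrom) &
      recs$arm1_start <= w$end & recs$arm2_end >= w$start
    r <- recs[sel, , drop = FALSE]
    if (nrow(r)) r[which.max(r$arm_len), , drop = FALSE] else r
  }
  # does the other parent retain the arm sequence without the full IR?
  arm_retained <- function(w, have_rec, src_parent) {
    if (is.null(genomes)) return(NA)
    other <- if (src_parent == "P1") "P2" else "P1"
    src <- genomes$genomes[[src_parent]][[w$chrom]]
    g <- genomes$genomes[[other]][[w$chrom]]
    win <- substring(g, max(1, w$start), min(nchar(g), w$end))
    arm <- substring(src, have_rec$arm1_start, have_rec$arm1_end)
    length(Biostrings::matchPattern(
      arm, win, max.mismatch = ceiling(0.1 * nchar(arm)))) > 0
  }
  out <- lapply(seq_len(nrow(loci)), function(i) {
    w <- loci[i, ]
    r1 <- in_window(lirs_p1, w); r2 <- in_window(lirs_p2, w)
    p1 <- nrow(r1) == 1; p2 <- nrow(r2) == 1
    h1 <- p1 && r1$hairpin_competent
    h2 <- p2 && r2$hairpin_competent
    other <- NA_character_
    cls <- if (h1 && h2) "both-hairpin"
      else if (xor(h1, h2)) "one-hairpin"
      else if (p1 || p2) "arm-lost"      # structure present but no hairpin
      else "absent"
    hp <- if (h1 && !h2) "P1" else if (h2 && !h1) "P2" else NA_character_
    if (cls == "one-hairpin") {
      other_full <- if (hp == "P1") p2 else p1
      if (other_full) other <- "long-spacer"
      else {
        ret <- arm_retained(w, if (hp == "P1") r1 else r2, hp)
        other <- if (isTRUE(ret)) "arm-only"
                 else if (isFALSE(ret)) "none" else NA_character_
      }
    }
    data.frame(locus = w$name, class = cls, hairpin_parent = hp,
               other_structure = other,
               p1_spacer = if (p1) r1$spacer_len else NA_integer_,
               p2_spacer = if (p2) r2$spacer_len else NA_integer_)
  })
  res <- do.call(rbind, out)
  if (any(res$class == "absent"))
    warning("unmatched locus/loci labeled 'absent': ",
            paste(res$locus[res$class == "absent"], collapse = ", "))
  res
}

#' Quantify LIR expression from mRNA reads
#'
#' Reads are matched exactly (either strand, at most one placement counted
#' per read) against the genotype-appropriate LIR reference: P1-genotype
#' individuals against the P1 copy, P2 against the P2 copy, heterozygotes
#' against both. The value is matched reads divided by the library total in
#' millions.
#'
#' @param mrna_libs named list per individual: list(reads, total).
#' @param lir_refs list(P1 = sequence or NULL, P2 = sequence or NULL).
#' @param genotypes named genotype vector over {"P1","P2","HET"} aligned with
#'   `mrna_libs`.
#' @return named numeric vector of reads-per-million (NA for individuals with
#'   zero total reads, excluded with a warning).
#' @export
quantify_lir_expression <- function(mrna_libs, lir_refs, genotypes) {
  stopifnot(length(mrna_libs) == length(genotypes))
  refs_for <- function(g) {
    r <- switch(g, P1 = lir_refs["P1"], P2 = lir_refs["P2"],
                HET = lir_refs[c("P1", "P2")])
    unlist(Filter(Negate(is.null), r))
  }
  out <- vapply(seq_along(mrna_libs), function(i) {
    lib <- mrna_libs[[i]]
    if (lib$total == 0) return(NA_real_)
    if (length(lib$reads) == 0) return(0)
    refs <- refs_for(genotypes[i])
    if (length(refs) == 0) return(0)
    subj <- paste(c(refs, revcomp(refs)), collapse = "NNNN")
    tab <- table(lib$reads)
    hit <- vapply(names(tab), function(r) grepl(r, subj, fixed = TRUE),
                  logical(1))
    sum(tab[hit]) / (lib$total / 1e6)
  }, numeric(1))
  names(out) <- names(mrna_libs)
  if (anyNA(out))
    warning("individuals with zero total reads excluded: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Associate expression values with genotype groups
#'
#' Per-group median and quartiles plus a two-sided Wilcoxon rank-sum test for
#' every pair of nonempty groups (exact for small tie-free samples, normal
#' approximation with tie correction otherwise, as in [stats::wilcox.test()]).
#'
#' @param values numeric vector.
#' @param genotypes factor/character of the same length.
#' @return list: `summary` (group, n, q1, median, q3), `tests`
#'   (group1, group2, p_value).
#' @export
associate_expression_genotype <- function(values, genotypes) {
  keep <- is.finite(values) & !is.na(genotypes)
  values <- values[keep]; genotypes <- as.character(genotypes)[keep]
  groups <- split(values, genotypes)
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need at least 2 nonempty genotype groups")
  summ <- data.frame(
    group = names(groups),
    n = lengths(groups),
    q1 = vapply(groups, function(x) unname(stats::quantile(x, .25)),
                numeric(1)),
    median = vapply(groups, stats::median, numeric(1)),
    q3 = vapply(groups, function(x) unname(stats::quantile(x, .75)),
                numeric(1)),
    row.names = NULL)
  prs <- utils::combn(names(groups), 2)
  tests <- data.frame(
    group1 = prs[1, ], group2 = prs[2, ],
    p_value = apply(prs, 2, function(p)
      suppressWarnings(stats::wilcox.test(groups[[p[1]]], groups[[p[2]]],
                                          alternative = "two.sided")$p.value)))
  list(summary = summ, tests = tests)
}

#' Correlate sRNA trait expression with LIR expression
#'
#' @param srna_expr traits x individuals matrix.
#' @param lir_expr numeric vector over the same individuals.
#' @return named numeric vector of Pearson correlation coefficients; traits
#'   (or a LIR) with zero variance yield NA (undefined), not 0.
#' @export
correlate_srna_lir <- function(srna_expr, lir_expr) {
  stopifnot(ncol(srna_expr) == length(lir_expr))
  ok <- is.finite(lir_expr)
  vapply(rownames(srna_expr) %||% seq_len(nrow(srna_expr)), function(tr) {
    y <- srna_expr[tr, ok]; x <- lir_expr[ok]
    use <- is.finite(y)
    if (sum(use) < 3) return(NA_real_)
    if (stats::var(y[use]) == 0 || stats::var(x[use]) == 0) return(NA_real_)
    stats::cor(x[use], y[use])
  }, numeric(1))
}
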
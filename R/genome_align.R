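# Alignment of trait sequences to the two parental genomes, local/distant
# resolution of QTLs, and authentication of multi-mapped alignments.

as_dnastringset <- function(genome) {
  if (inherits(genome, "DNAStringSet")) genome
  else Biostrings::DNAStringSet(unlist(genome))
}

#' Align sRNA tags to one or both parental genomes
#'
#' Exact (0-mismatch) matching uses a preprocessed dictionary per tag length;
#' the 1-mismatch mode verifies per tag. Both strands are searched; minus
#' strand hits are reported in plus-strand coordinates (1-based inclusive).
#' In "unique" mode a tag's hits in a genome are reported only when exactly
#' one 0-mismatch hit exists genome-wide in that genome.
#'
#' @param tags character vector of tag sequences (optionally named).
#' @param genomes a `genome_pair`, or a named list of genomes, or a single
#'   genome (named character vector of chromosomes / DNAStringSet).
#' @param max_mismatch 0 or 1.
#' @param report "all" (every hit up to `max_mismatch`) or "unique".
#' @return data.frame: query, genome, chrom, start, end, strand, mismatches.
#' @export
align_tags <- function(tags, genomes, max_mismatch = 0,
                       report = c("all", "unique")) {
  report <- match.arg(report)
  stopifnot(max_mismatch %in% 0:1)
  qnames <- names(tags) %||% tags
  names(tags) <- qnames
  glist <- if (inherits(genomes, "genome_pair")) genomes$genomes
           else if (is.list(genomes) && !inherits(genomes, "DNAStringSet"))
             genomes
           else list(genome = genomes)
  res <- list()
  for (gn in names(glist)) {
    subj <- as_dnastringset(glist[[gn]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tags else
        stats::setNames(revcomp(tags), qnames)
      for (w in unique(nchar(pat))) {
        idx <- which(nchar(pat) == w)
        pd <- Biostrings::PDict(pat[idx])
        for (ci in seq_along(subj)) {
          mi <- Biostrings::matchPDict(pd, subj[[ci]])
          nh <- S4Vectors::elementNROWS(mi)
          if (sum(nh) == 0) next
          ir <- unlist(mi)
          res[[length(res) + 1]] <- data.frame(
            query = qnames[idx][rep(seq_along(nh), nh)],
            genome = gn,
            chrom = names(subj)[ci],
            start = BiocGenerics::start(ir), end = BiocGenerics::end(ir),
            strand = strand, mismatches = 0L, stringsAsFactors = FALSE)
        }
      }
    }
    if (max_mismatch == 1) {
      for (qi in seq_along(tags)) {
        for (strand in c("+", "-")) {
          p <- if (strand == "+") tags[qi] else revcomp(tags[qi])
          for (ci in seq_along(subj)) {
            m <- Biostrings::matchPattern(p, subj[[ci]], max.mismatch = 1)
            if (length(m) == 0) next
            mm <- vapply(seq_along(m), function(h)
              sum(strsplit(as.character(m[[h]]), "")[[1]] !=
                    strsplit(p, "")[[1]]), integer(1))
            keep <- mm == 1L
            if (!any(keep)) next
            res[[length(res) + 1]] <- data.frame(
              query = qnames[qi], genome = gn,
              chrom = names(subj)[ci],
              start = BiocGenerics::start(m)[keep],
              end = BiocGenerics::end(m)[keep],
              strand = strand, mismatches = 1L, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  hits <- if (length(res)) do.call(rbind, res) else
    data.frame(query = character(0), genome = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), mismatches = integer(0))
  if (report == "unique") {
    zero <- hits[hits$mismatches == 0L, , drop = FALSE]
    key <- paste(zero$query, zero$genome)
    hits <- zero[key %in% names(which(table(key) == 1)), , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Align cluster sequences to a genome
#'
#' Near-exact placement: each cluster is matched against both strands with a
#' mismatch budget implied by `min_identity` (substitutions and small indels);
#' identity is recomputed per hit and hits below `min_identity` or covering
#' less than `min_coverage` of the query are dropped. Queries with more than
#' one retained hit are discarded when `unique_only`.
#'
#' @param clusters character vector (or data.frame with `sequence`, `id`).
#' @param genome named character vector of chromosomes or DNAStringSet.
#' @param min_identity,min_coverage alignment quality filters.
#' @param unique_only drop multi-hit queries.
#' @return data.frame: query, chrom, start, end, strand, identity, coverage.
#' @export
align_clusters <- function(clusters, genome, min_identity = 0.9,
                           min_coverage = 0.85, unique_only = TRUE) {
  if (is.data.frame(clusters)) {
    ids <- clusters$id; seqs <- clusters$sequence
  } else {
    ids <- names(clusters) %||% paste0("cl", seq_along(clusters))
    seqs <- as.character(clusters)
  }
  subj <- as_dnastringset(genome)
  res <- list()
  for (qi in seq_along(seqs)) {
    qlen <- nchar(seqs[qi])
    budget <- floor((1 - min_identity) * qlen)
    for (strand in c("+", "-")) {
      p <- if (strand == "+") seqs[qi] else revcomp(seqs[qi])
      for (ci in seq_along(subj)) {
        m <- Biostrings::matchPattern(p, subj[[ci]], max.mismatch = budget,
                                      with.indels = TRUE)
        if (length(m) == 0) next
        for (h in seq_along(m)) {
          hs <- as.character(m[[h]])
          pa <- Biostrings::pairwiseAlignment(p, hs, type = "global")
          ident <- Biostrings::pid(pa, type = "PID1") / 100
          cov <- Biostrings::nmatch(pa) / qlen
          if (ident < min_identity || cov < min_coverage) next
          res[[length(res) + 1]] <- data.frame(
            query = ids[qi], chrom = names(subj)[ci],
            start = BiocGenerics::start(m)[h],
            end = BiocGenerics::end(m)[h], strand = strand,
            identity = ident, coverage = cov, stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(res)) do.call(rbind, res) else
    data.frame(query = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0), identity = numeric(0),
               coverage = numeric(0))
  # near-exact matching reports many overlapping windows around one locus;
  # group overlapping placements per query and keep the best per locus
  if (nrow(hits)) {
    hits <- hits[order(hits$query, hits$chrom, hits$start, -hits$identity), ,
                 drop = FALSE]
    grp <- integer(nrow(hits)); gid <- 0L
    prev_end <- -1; prev_key <- ""
    for (i in seq_len(nrow(hits))) {
      key <- paste(hits$query[i], hits$chrom[i])
      if (key != prev_key || hits$start[i] > prev_end) {
        gid <- gid + 1L
        prev_end <- hits$end[i]
      } else prev_end <- max(prev_end, hits$end[i])
      prev_key <- key
      grp[i] <- gid
    }
    best <- unlist(lapply(split(seq_len(nrow(hits)), grp), function(ix)
      ix[order(-hits$identity[ix], -hits$coverage[ix], hits$start[ix])][1]))
    hits <- hits[sort(best), , drop = FALSE]
  }
  if (unique_only && nrow(hits)) {
    tab <- table(hits$query)
    hits <- hits[hits$query %in% names(tab)[tab == 1], , drop = FALSE]
  }
  rownames(hits) <- NULL
  hits
}

#' Resolve a QTL as local or distant from its trait's alignments
#'
#' "local": some alignment of the trait lies on the peak bin's chromosome
#' within `max_dist` of the bin interval (rule "window"), or inside the
#' genomic span of the support interval (rule "support"). "distant":
#' alignments exist but none qualifies. "unresolved": no alignment.
#'
#' @param qtls data.frame of calls (peak_bin, support_start, support_end) as
#'   from [scan_traits()], with a `trait` column.
#' @param hits alignment data.frame from [align_tags()] or
#'   [align_clusters()]; `query` must match `trait`.
#' @param binmap a `bin_map` (genomic bin coordinates).
#' @param max_dist window size in bp for the "window" rule.
#' @param rule "window" or "support".
#' @return the `qtls` data.frame with a `mode` column appended.
#' @export
resolve_local_distant <- function(qtls, hits, binmap, max_dist = 1e6,
                                  rule = c("window", "support")) {
  rule <- match.arg(rule)
  bins <- binmap$bins
  mode <- character(nrow(qtls))
  for (i in seq_len(nrow(qtls))) {
    h <- hits[hits$query == qtls$trait[i], , drop = FALSE]
    if (nrow(h) == 0) { mode[i] <- "unresolved"; next }
    if (rule == "window") {
      b <- bins[bins$bin == qtls$peak_bin[i], ]
      lo <- b$start - max_dist; hi <- b$end + max_dist
    } else {
      bs <- bins[bins$bin >= qtls$support_start[i] &
                   bins$bin <= qtls$support_end[i], ]
      b <- bs[1, ]
      lo <- min(bs$start); hi <- max(bs$end)
    }
    local <- any(h$chrom == b$chrom & h$end >= lo & h$start <= hi)
    mode[i] <- if (local) "local" else "distant"
  }
  qtls$mode <- mode
  qtls
}

#' Authenticate alignments of a multi-mapped trait using its QTLs
#'
#' For a trait with at least one local QTL, alignments within `max_dist` of a
#' local QTL's bin are kept as authentic; all others are dropped. When
#' authentic hits exist in both parental genomes, hits in a genome are kept
#' only if that genome has at least one hit inside the window (cross-genome
#' consistency). An empty result means the trait stays multimapped-unresolved.
#'
#' @param hits alignment data.frame for one trait (columns as
#'   [align_tags()]; a `genome` column is used for the consistency rule when
#'   present).
#' @param qtls that trait's QTL calls with a `mode` column (see
#'   [resolve_local_distant()]).
#' @param binmap a `bin_map`.
#' @param max_dist local window in bp.
#' @return subset of `hits`.
#' @export
authenticate_alignments <- function(hits, qtls, binmap, max_dist = 1e6) {
  stopifnot(nrow(qtls) >= 1)
  loc <- qtls[qtls$mode == "local", , drop = FALSE]
  if (nrow(loc) == 0) return(hits[0, , drop = FALSE])
  bins <- binmap$bins
  keep <- rep(FALSE, nrow(hits))
  for (i in seq_len(nrow(loc))) {
    b <- bins[bins$bin == loc$peak_bin[i], ]
    keep <- keep | (hits$chrom == b$chrom &
                      hits$end >= b$start - max_dist &
                      hits$start <= b$end + max_dist)
  }
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
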
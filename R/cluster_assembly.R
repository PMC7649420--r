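# sRNA cluster assembly: a greedy seed-and-extend overlap assembler over
# collapsed reads, single-linkage merging of contigs into cluster consensi,
# unique-placement read counting, median-of-ratios size factors, and the
# sc-trait filter.

KMER_IDX <- 16L  # indexing width for overlap candidate lookup

make_kmer_env <- function(keys) {
  env <- new.env(hash = TRUE, parent = emptyenv(), size = length(keys))
  for (i in seq_along(keys)) {
    k <- keys[i]
    env[[k]] <- c(env[[k]], i)
  }
  env
}

#' Greedy assembly of collapsed sRNA reads into contigs
#'
#' Seeds at the most abundant unused read (ties broken lexicographically) and
#' extends the 3' end, then the 5' end, by the unused read whose
#' prefix/suffix overlaps the contig terminus by at least `min_overlap`
#' bases, preferring the longest overlap, then the highest abundance, then
#' the lexicographically smallest sequence. Placed reads and reads contained
#' in a finished contig are consumed. Contigs shorter than `min_contig` are
#' discarded (apply [filter_contigs()] afterwards for the final length
#' filter).
#'
#' @param reads character vector of reads, or a named integer vector of
#'   collapsed counts (names = sequences).
#' @param min_overlap minimum suffix-prefix overlap (bases).
#' @param min_contig minimum contig length retained by the assembler.
#' @return data.frame: contig id, sequence, length, support (total abundance
#'   of member reads), n_members; member sequences in attribute "members".
#' @export
assemble_clusters <- function(reads, min_overlap = 16, min_contig = 50) {
  if (is.null(names(reads))) {
    tab <- table(reads)
    counts <- as.integer(tab); seqs <- names(tab)
  } else {
    seqs <- names(reads); counts <- as.integer(reads)
  }
  stopifnot(min_overlap >= KMER_IDX)
  o <- order(-counts, seqs)
  seqs <- seqs[o]; counts <- counts[o]
  n <- length(seqs)
  lens <- nchar(seqs)
  used <- rep(FALSE, n)
  pre_env <- make_kmer_env(substring(seqs, 1, KMER_IDX))
  suf_env <- make_kmer_env(substring(seqs, lens - KMER_IDX + 1, lens))
  max_len <- max(lens)

  pick <- function(cand) cand[order(-counts[cand], seqs[cand])][1]

  contigs <- list(); members <- list(); support <- integer(0)
  for (s in seq_len(n)) {
    if (used[s]) next
    used[s] <- TRUE
    contig <- seqs[s]
    placed <- s
    # 3' extension
    repeat {
      L <- nchar(contig)
      ext <- NA_integer_; ext_ov <- 0L
      ov_top <- min(L, max_len - 1L)
      if (ov_top < min_overlap) break
      for (ov in ov_top:min_overlap) {
        key <- substring(contig, L - ov + 1L, L - ov + KMER_IDX)
        cand <- pre_env[[key]]
        cand <- cand[!used[cand] & lens[cand] > ov]
        if (length(cand) == 0) next
        cand <- cand[substring(seqs[cand], 1, ov) ==
                       substring(contig, L - ov + 1L, L)]
        if (length(cand)) { ext <- pick(cand); ext_ov <- ov; break }
      }
      if (is.na(ext)) break
      used[ext] <- TRUE; placed <- c(placed, ext)
      contig <- paste0(contig, substring(seqs[ext], ext_ov + 1L))
    }
    # 5' extension
    repeat {
      ext <- NA_integer_; ext_ov <- 0L
      ov_top <- min(nchar(contig), max_len - 1L)
      if (ov_top < min_overlap) break
      for (ov in ov_top:min_overlap) {
        key <- substring(contig, ov - KMER_IDX + 1L, ov)
        cand <- suf_env[[key]]
        cand <- cand[!used[cand] & lens[cand] > ov]
        if (length(cand) == 0) next
        cand <- cand[substring(seqs[cand], lens[cand] - ov + 1L,
                               lens[cand]) == substring(contig, 1, ov)]
        if (length(cand)) { ext <- pick(cand); ext_ov <- ov; break }
      }
      if (is.na(ext)) break
      used[ext] <- TRUE; placed <- c(placed, ext)
      contig <- paste0(substring(seqs[ext], 1, lens[ext] - ext_ov), contig)
    }
    if (nchar(contig) < min_contig) next
    # consume reads contained in the finished contig
    Lc <- nchar(contig)
    if (Lc >= KMER_IDX) {
      cand <- integer(0)
      for (p in seq_len(Lc - KMER_IDX + 1L)) {
        hit <- pre_env[[substring(contig, p, p + KMER_IDX - 1L)]]
        if (is.null(hit)) next
        hit <- hit[!used[hit] & lens[hit] <= Lc - p + 1L]
        if (length(hit) == 0) next
        hit <- hit[substring(contig, p, p + lens[hit] - 1L) == seqs[hit]]
        if (length(hit) == 0) next
        cand <- c(cand, hit)
        used[hit] <- TRUE
      }
      placed <- c(placed, unique(cand))
    }
    contigs[[length(contigs) + 1]] <- contig
    members[[length(members) + 1]] <- seqs[placed]
    support <- c(support, sum(counts[placed]))
  }
  out <- data.frame(id = if (length(contigs))
                      paste0("ctg", seq_along(contigs)) else character(0),
                    sequence = unlist(contigs) %||% character(0),
                    length = nchar(unlist(contigs) %||% character(0)),
                    support = support, stringsAsFactors = FALSE)
  out$n_members <- lengths(members)
  attr(out, "members") <- members
  out
}

#' Final contig length filter
#'
#' @param contigs data.frame from [assemble_clusters()] or [merge_contigs()].
#' @param min_len minimum length kept (contigs shorter than this are removed;
#'   a contig of exactly `min_len` is kept).
#' @return filtered data.frame.
#' @export
filter_contigs <- function(contigs, min_len = 60) {
  contigs[nchar(contigs$sequence) >= min_len, , drop = FALSE]
}

# ungapped identity of two equal-length strings
hamming_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("length mismatch")
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  mean(va == vb)
}

#' Merge contigs into non-redundant clusters
#'
#' Single-linkage clustering of contigs that share an ungapped overlap of at
#' least `min_overlap_bp` bases at identity >= `min_identity` on either
#' strand, followed by a majority-vote consensus over the aligned layout of
#' each cluster.
#'
#' @param contigs data.frame from [assemble_clusters()] or a character vector
#'   of contig sequences.
#' @param min_identity minimum overlap identity.
#' @param min_overlap_bp minimum overlap length.
#' @param seed_k exact seed length used to find candidate overlaps (must not
#'   exceed the mismatch-free stretch guaranteed by `min_identity` over
#'   `min_overlap_bp`).
#' @return data.frame: cluster id, sequence (consensus), length, n_contigs;
#'   member contig indices in attribute "members".
#' @export
merge_contigs <- function(contigs, min_identity = 0.94, min_overlap_bp = 40,
                          seed_k = 12) {
  seqs <- if (is.data.frame(contigs)) contigs$sequence else contigs
  stopifnot(length(seqs) > 0)
  n <- length(seqs)
  lens <- nchar(seqs)

  # seed table over both strands: kmer -> (contig, position, strand)
  entries <- list()
  for (i in seq_len(n)) {
    if (lens[i] < seed_k) next
    np <- lens[i] - seed_k + 1L
    entries[[length(entries) + 1]] <- data.frame(
      kmer = substring(seqs[i], seq_len(np), seq_len(np) + seed_k - 1L),
      contig = i, pos = seq_len(np), strand = "+")
    rcs <- revcomp(seqs[i])
    entries[[length(entries) + 1]] <- data.frame(
      kmer = substring(rcs, seq_len(np), seq_len(np) + seed_k - 1L),
      contig = i, pos = seq_len(np), strand = "-")
  }
  ent <- do.call(rbind, entries)

  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  # layout edges: (i, j, offset, orient): oriented sequence of j starts at
  # offset relative to i's coordinate system
  edges <- list()
  check_pair <- function(i, j, off, orient) {
    sj <- if (orient == "+") seqs[j] else revcomp(seqs[j])
    a1 <- max(1L, 1L + off); a2 <- min(lens[i], off + nchar(sj))
    if (a2 - a1 + 1L < min_overlap_bp) return(FALSE)
    sub_i <- substring(seqs[i], a1, a2)
    sub_j <- substring(sj, a1 - off, a2 - off)
    hamming_identity(sub_i, sub_j) >= min_identity
  }
  # candidate pairs from shared seeds between i(+) and j(+/-), i < j
  fwd <- ent[ent$strand == "+", ]
  sp_f <- split(seq_len(nrow(fwd)), fwd$kmer)
  sp_all <- split(seq_len(nrow(ent)), ent$kmer)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(sp_f)) {
    rows_i <- fwd[sp_f[[k]], ]
    rows_j <- ent[sp_all[[k]], ]
    for (a in seq_len(nrow(rows_i))) for (b in seq_len(nrow(rows_j))) {
      i <- rows_i$contig[a]; j <- rows_j$contig[b]
      if (i >= j) next
      off <- rows_i$pos[a] - rows_j$pos[b]
      key <- paste(i, j, off, rows_j$strand[b])
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      if (check_pair(i, j, off, rows_j$strand[b])) {
        union_(i, j)
        edges[[length(edges) + 1]] <-
          list(i = i, j = j, off = off, orient = rows_j$strand[b])
      }
    }
  }

  comp <- vapply(seq_len(n), find, integer(1))
  out <- list(); memb <- list()
  for (root in unique(comp)) {
    ids <- which(comp == root)
    if (length(ids) == 1) {
      out[[length(out) + 1]] <- seqs[ids]
      memb[[length(memb) + 1]] <- ids
      next
    }
    # BFS layout from the longest member
    rep_id <- ids[which.max(lens[ids])]
    off <- stats::setNames(rep(NA_integer_, length(ids)), ids)
    ori <- stats::setNames(rep(NA_character_, length(ids)), ids)
    off[as.character(rep_id)] <- 0L; ori[as.character(rep_id)] <- "+"
    queue <- rep_id
    eds <- edges[vapply(edges, function(e)
      e$i %in% ids && e$j %in% ids, logical(1))]
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (e in eds) {
        other <- if (e$i == cur) e$j else if (e$j == cur) e$i else next
        if (!is.na(off[as.character(other)])) next
        # edge stores j relative to i in i's forward frame
        if (e$i == cur) {
          o2 <- if (ori[as.character(cur)] == "+") e$orient else
            if (e$orient == "+") "-" else "+"
          d2 <- if (ori[as.character(cur)] == "+")
            off[as.character(cur)] + e$off else
            off[as.character(cur)] + (lens[cur] - (e$off + lens[other]))
        } else {
          o2 <- if (ori[as.character(cur)] == "+") e$orient else
            if (e$orient == "+") "-" else "+"
          base_off <- -e$off
          d2 <- if (ori[as.character(cur)] == "+")
            off[as.character(cur)] + base_off else
            off[as.character(cur)] + (lens[cur] - (base_off + lens[other]))
        }
        off[as.character(other)] <- d2
        ori[as.character(other)] <- o2
        queue <- c(queue, other)
      }
    }
    shift <- min(off, na.rm = TRUE)
    off <- off - shift
    width <- max(off + lens[as.integer(names(off))])
    votes <- matrix(0L, 4, width, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (id in ids) {
      s <- if (ori[as.character(id)] == "+") seqs[id] else revcomp(seqs[id])
      o0 <- off[as.character(id)]
      ch <- strsplit(s, "")[[1]]
      idx <- cbind(match(ch, rownames(votes)), o0 + seq_along(ch))
      votes[idx] <- votes[idx] + 1L
    }
    cons <- rownames(votes)[apply(votes, 2, which.max)]
    out[[length(out) + 1]] <- paste(cons, collapse = "")
    memb[[length(memb) + 1]] <- ids
  }
  res <- data.frame(id = paste0("cl", seq_along(out)),
                    sequence = unlist(out),
                    length = nchar(unlist(out)),
                    n_contigs = lengths(memb), stringsAsFactors = FALSE)
  attr(res, "members") <- memb
  res
}

#' Count reads against cluster sequences with unique placement
#'
#' A read contributes its count to a cluster when it matches (exact,
#' either strand) that cluster and no other; multi-cluster reads are
#' discarded, mirroring unique-alignment read counting.
#'
#' @param libraries named list of collapsed count vectors (or an `srna_tags`
#'   object).
#' @param clusters character vector of cluster sequences (or a data.frame
#'   with a `sequence` column).
#' @return list of class `cluster_counts`: `counts` (clusters x libraries),
#'   `assigned` (tag -> cluster index, NA for unplaced/multi).
#' @export
count_cluster_reads <- function(libraries, clusters) {
  if (inherits(libraries, "srna_tags")) {
    counts_mat <- libraries$counts
  } else {
    counts_mat <- collapse_reads(libraries)$counts
  }
  cl_seq <- if (is.data.frame(clusters)) clusters$sequence else clusters
  ncl <- length(cl_seq)
  tags <- rownames(counts_mat)
  subj <- Biostrings::DNAStringSet(c(cl_seq, revcomp(cl_seq)))
  hit_clusters <- vector("list", length(tags))
  for (w in unique(nchar(tags))) {
    idx <- which(nchar(tags) == w)
    pd <- Biostrings::PDict(tags[idx])
    wh <- Biostrings::vwhichPDict(pd, subj)
    for (s in seq_along(wh)) {
      cl <- ((s - 1L) %% ncl) + 1L
      for (p in wh[[s]]) {
        gi <- idx[p]
        hit_clusters[[gi]] <- c(hit_clusters[[gi]], cl)
      }
    }
  }
  nhit <- vapply(hit_clusters, function(x) length(unique(x)), integer(1))
  assigned <- ifelse(nhit == 1,
                     vapply(hit_clusters, function(x)
                       if (length(x)) x[[1]] else NA_integer_, integer(1)),
                     NA_integer_)
  cm <- matrix(0, ncl, ncol(counts_mat),
               dimnames = list(if (is.data.frame(clusters)) clusters$id
                               else paste0("cl", seq_len(ncl)),
                               colnames(counts_mat)))
  ok <- !is.na(assigned)
  if (any(ok)) {
    agg <- rowsum(counts_mat[ok, , drop = FALSE], assigned[ok])
    cm[as.integer(rownames(agg)), ] <- agg
  }
  structure(list(counts = cm,
                 assigned = stats::setNames(assigned, tags)),
            class = "cluster_counts")
}

#' Median-of-ratios size factors
#'
#' `g_i` is the geometric mean of row i over libraries (rows with any zero
#' excluded); `s_j` is the median over those rows of `k_ij / g_i`.
#'
#' @param raw clusters x libraries count matrix (or `cluster_counts`).
#' @param fallback when no all-positive row exists: if FALSE (default),
#'   error; if TRUE, use geometric means over positive entries only and warn.
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(raw, fallback = FALSE) {
  if (inherits(raw, "cluster_counts")) raw <- raw$counts
  pos <- rowSums(raw <= 0) == 0
  if (!any(pos)) {
    if (!fallback)
      stop("no cluster has positive counts in every library; ",
           "rerun with fallback = TRUE for a positive-entry pseudo-reference")
    warning("no all-positive row; using positive-entry geometric means")
    lg <- log(raw); lg[!is.finite(lg)] <- NA
    g <- exp(rowMeans(lg, na.rm = TRUE))
    ratios <- sweep(raw, 1, g, "/")
    ratios[raw <= 0] <- NA
    s <- apply(ratios, 2, stats::median, na.rm = TRUE)
  } else {
    sub <- raw[pos, , drop = FALSE]
    g <- exp(rowMeans(log(sub)))
    s <- apply(sweep(sub, 1, g, "/"), 2, stats::median)
  }
  if (any(!is.finite(s)))
    stop("size factor undefined for library/libraries ",
         paste(colnames(raw)[!is.finite(s)], collapse = ", "),
         " (no positive counts shared with the reference)")
  if (any(s <= 0)) stop("non-positive size factor computed")
  s
}

#' Normalize a count matrix by size factors
#'
#' @param raw clusters x libraries count matrix (or `cluster_counts`).
#' @param s size factors (default computed by [size_factors()]).
#' @return normalized matrix `k_ij / s_j`.
#' @export
normalize_counts <- function(raw, s = NULL) {
  if (inherits(raw, "cluster_counts")) raw <- raw$counts
  s <- s %||% size_factors(raw)
  sweep(raw, 2, s, "/")
}

#' Define sc-traits from normalized cluster expression
#'
#' Clusters with normalized value >= `min_value` in strictly more than
#' `min_libs` libraries are retained.
#'
#' @param normalized clusters x libraries normalized matrix.
#' @param min_value expression floor.
#' @param min_libs strict lower bound on qualifying libraries.
#' @return a `trait_set` of kind "sc-trait".
#' @export
define_sc_traits <- function(normalized, min_value = 6, min_libs = 25) {
  keep <- rowSums(normalized >= min_value) > min_libs
  structure(list(values = normalized[keep, , drop = FALSE],
                 presence = normalized[keep, , drop = FALSE] >= min_value,
                 kind = "sc-trait", n_total = nrow(normalized),
                 n_retained = sum(keep)),
            class = "trait_set")
}
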
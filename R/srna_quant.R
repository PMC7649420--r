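# Reference-free sRNA quantification: collapse reads to unique tags, RPM
# normalization, s-trait definition, nucleotide composition and whole-genome
# composition traits, and feature-distribution comparison.

#' Collapse reads into a unique-tag count matrix
#'
#' Deduplicates reads per library, then unions tags across libraries. Input
#' libraries may be raw read vectors or already-collapsed named count vectors.
#' U is normalized to T at ingest; reads outside the length range or with
#' non-ACGTU characters are dropped and reported.
#'
#' @param libraries named list; each element either a character vector of
#'   reads or a named integer vector (names = sequences, values = counts).
#' @param length_range inclusive tag length range.
#' @return list of class `srna_tags`: `counts` (tags x libraries integer
#'   matrix, rownames = sequences), `totals` (per-library in-range read
#'   totals), `rejects` (per-library counts of dropped reads).
#' @export
collapse_reads <- function(libraries, length_range = c(18, 30)) {
  stopifnot(!is.null(names(libraries)))
  per_lib <- lapply(libraries, function(lib) {
    if (is.null(names(lib))) {
      tab <- table(lib)
      cnt <- stats::setNames(as.integer(tab), names(tab))
    } else {
      cnt <- lib
      stopifnot(all(cnt >= 0))
    }
    seqs <- toupper(chartr("U", "T", names(cnt)))
    names(cnt) <- seqs
    bad <- grepl("[^ACGT]", seqs)
    short <- !bad & (nchar(seqs) < length_range[1] |
                       nchar(seqs) > length_range[2])
    keep <- cnt[!bad & !short]
    # merge duplicates created by U->T normalization
    if (anyDuplicated(names(keep)))
      keep <- tapply(keep, names(keep), sum)
    list(counts = keep,
         rejected = sum(cnt[bad]), out_of_range = sum(cnt[short]))
  })
  all_tags <- unique(unlist(lapply(per_lib, function(x) names(x$counts)),
                            use.names = FALSE))
  counts <- matrix(0L, length(all_tags), length(libraries),
                   dimnames = list(all_tags, names(libraries)))
  for (j in seq_along(per_lib)) {
    cc <- per_lib[[j]]$counts
    counts[match(names(cc), all_tags), j] <- as.integer(cc)
  }
  rejects <- data.frame(
    library = names(libraries),
    rejected = vapply(per_lib, `[[`, numeric(1), "rejected"),
    out_of_range = vapply(per_lib, `[[`, numeric(1), "out_of_range"),
    row.names = NULL)
  structure(list(counts = counts, totals = colSums(counts),
                 rejects = rejects),
            class = "srna_tags")
}

#' Reads-per-million normalization
#'
#' `rpm[i,j] = counts[i,j] * 1e6 / totals[j]`. When `totals` are the column
#' sums, each RPM column sums to exactly 1e6 (up to float rounding).
#'
#' @param counts tags x libraries count matrix (or an `srna_tags` object).
#' @param totals per-library total read counts; defaults to column sums.
#' @return RPM matrix of the same shape.
#' @export
rpm_normalize <- function(counts, totals = NULL) {
  if (inherits(counts, "srna_tags")) {
    totals <- totals %||% counts$totals
    counts <- counts$counts
  }
  totals <- totals %||% colSums(counts)
  bad <- totals == 0 & colSums(counts) > 0
  if (any(bad))
    stop("zero library total with nonzero counts: ",
         paste(colnames(counts)[bad], collapse = ", "))
  sweep(counts, 2, ifelse(totals == 0, 1, totals), "/") * 1e6
}

#' Define s-traits by population presence
#'
#' A tag is an s-trait when it is present (raw count >= 1) in strictly more
#' than `presence_min` individuals.
#'
#' @param rpm tags x libraries RPM matrix.
#' @param counts matching raw count matrix used for the presence call; if
#'   omitted, presence is `rpm > 0` (equivalent under RPM's zero-preservation).
#' @param presence_min strict lower bound on the number of individuals a trait
#'   must be present in; default `floor(n/2)` (48 for the 98-individual case).
#' @return list of class `trait_set`: `values` (traits x individuals),
#'   `presence`, `kind`, `n_total`, `n_retained`.
#' @export
define_s_traits <- function(rpm, counts = NULL, presence_min = NULL) {
  n <- ncol(rpm)
  presence_min <- presence_min %||% floor(n / 2)
  pres <- if (is.null(counts)) rpm > 0 else counts >= 1
  keep <- rowSums(pres) > presence_min
  structure(list(values = rpm[keep, , drop = FALSE],
                 presence = pres[keep, , drop = FALSE],
                 kind = "s-trait", presence_min = presence_min,
                 n_total = nrow(rpm), n_retained = sum(keep)),
            class = "trait_set")
}

#' Per-position nucleotide composition
#'
#' @param tags character vector of tag sequences.
#' @param size tag length to profile; tags of other lengths are ignored.
#' @return list: `by_position` (size x 4 matrix of base fractions, rows sum
#'   to 1), `pooled` (all-position fractions), `n` tags used.
#' @export
nucleotide_composition <- function(tags, size) {
  tags <- tags[nchar(tags) == size]
  if (length(tags) == 0) {
    warning("no tags of size ", size)
    return(list(by_position = NULL, pooled = NULL, n = 0L))
  }
  mat <- matrix(unlist(strsplit(tags, "")), nrow = length(tags), byrow = TRUE)
  bases <- c("A", "C", "G", "T")
  byp <- t(apply(mat, 2, function(col)
    table(factor(col, levels = bases)) / length(col)))
  rownames(byp) <- paste0("pos", seq_len(size))
  pooled <- table(factor(mat, levels = bases)) / length(mat)
  list(by_position = byp, pooled = c(pooled), n = length(tags))
}

#' Whole-genome sRNA species composition traits
#'
#' Per library: the percentage of reads in each size class and the percentage
#' beginning with each 5' base. Size-class percentages sum to 100 per library.
#'
#' @param tags an `srna_tags` object or a tags x libraries count matrix with
#'   sequence rownames.
#' @param length_range size classes reported.
#' @return a `trait_set` of kind "composition": `values` is traits x
#'   libraries, trait rows named `size_18`..`size_30` and `first_A` etc.
#' @export
composition_traits <- function(tags, length_range = c(18, 30)) {
  counts <- if (inherits(tags, "srna_tags")) tags$counts else tags
  empty <- colSums(counts) == 0
  if (any(empty)) {
    warning("excluding empty libraries: ",
            paste(colnames(counts)[empty], collapse = ", "))
    counts <- counts[, !empty, drop = FALSE]
  }
  sizes <- nchar(rownames(counts))
  first <- substring(rownames(counts), 1, 1)
  tot <- colSums(counts)
  size_levels <- seq(length_range[1], length_range[2])
  size_pct <- do.call(rbind, lapply(size_levels, function(s)
    100 * colSums(counts[sizes == s, , drop = FALSE]) / tot))
  rownames(size_pct) <- paste0("size_", size_levels)
  bases <- c("A", "C", "G", "T")
  base_pct <- do.call(rbind, lapply(bases, function(b)
    100 * colSums(counts[first == b, , drop = FALSE]) / tot))
  rownames(base_pct) <- paste0("first_", bases)
  vals <- rbind(size_pct, base_pct)
  structure(list(values = vals, presence = vals > 0, kind = "composition",
                 n_total = nrow(vals), n_retained = nrow(vals)),
            class = "trait_set")
}

#' Chi-squared comparison of a feature distribution against a background
#'
#' Expected counts are the group total distributed according to the background
#' fractions. Categories with expected 0 and observed 0 are dropped; an
#' expected 0 with positive observed is given a 0.5 pseudo-expectation, kept
#' in the degrees of freedom, and flagged.
#'
#' @param group_counts named integer vector of observed category counts.
#' @param background_counts named vector over the same categories.
#' @return list of class `feature_table`: `table` (category, observed,
#'   expected), `statistic`, `df`, `p_value`, `pseudo` (flagged categories).
#' @export
compare_feature_distribution <- function(group_counts, background_counts) {
  stopifnot(length(group_counts) == length(background_counts))
  if (sum(group_counts) == 0) stop("group total is zero")
  if (sum(background_counts) == 0) stop("background total is zero")
  O <- group_counts
  E <- sum(O) * background_counts / sum(background_counts)
  drop <- E == 0 & O == 0
  O <- O[!drop]; E <- E[!drop]
  pseudo <- names(O)[E == 0 & O > 0]
  E[E == 0 & O > 0] <- 0.5
  stat <- sum((O - E)^2 / E)
  df <- length(O) - 1
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(table = data.frame(category = names(O) %||%
                                      seq_along(O),
                                    observed = as.numeric(O),
                                    expected = as.numeric(E),
                                    row.names = NULL),
                 statistic = stat, df = df, p_value = p, pseudo = pseudo),
            class = "feature_table")
}
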
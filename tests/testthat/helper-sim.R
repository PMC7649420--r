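# Shared fixtures, built in code. A small scenario is memoized per test run.

rnd_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

small_design <- function(seed = 11) {
  population_design(n_ril = 60, n_imf2 = 30, n_chrom = 2,
                    chrom_len = 250000L, markers_per_chrom = 40, seed = seed)
}

.sim_cache <- new.env(parent = emptyenv())

small_scenario <- function(seed = 11) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]])) {
    d <- small_design(seed)
    .sim_cache[[key]] <- simulate_scenario(
      d, n_neutral = 40, n_cis = 80, n_trans = 100)
  }
  .sim_cache[[key]]
}

# independent nested-OLS LOD oracle: plain lm() fits, no shared code with
# scan_trait beyond the model definition
oracle_lod <- function(y, xa, xd, bin_chrom, cofactors = integer(0),
                       window = 10) {
  n <- length(y)
  vapply(seq_len(ncol(xa)), function(b) {
    ac <- cofactors[!(bin_chrom[cofactors] == bin_chrom[b] &
                        abs(cofactors - b) <= window)]
    d0 <- as.data.frame(xa[, ac, drop = FALSE])
    names(d0) <- if (length(ac)) paste0("c", ac) else character(0)
    d1 <- cbind(d0, a = xa[, b], dd = xd[, b])
    # drop constant columns as the scan documents
    d0 <- d0[, vapply(d0, function(z) max(z) > min(z), logical(1)),
             drop = FALSE]
    d1 <- d1[, vapply(d1, function(z) max(z) > min(z), logical(1)),
             drop = FALSE]
    f0 <- if (ncol(d0)) lm(y ~ ., data = cbind(d0, y = y)) else lm(y ~ 1)
    f1 <- if (ncol(d1)) lm(y ~ ., data = cbind(d1, y = y)) else lm(y ~ 1)
    rss0 <- sum(residuals(f0)^2)
    rss1 <- sum(residuals(f1)^2)
    max(0, n / 2 * log10(rss0 / rss1))
  }, numeric(1))
}

# brute-force all-substring reverse-complement arm oracle for short sequences:
# maximal exact pairings per anti-diagonal
oracle_inverted_repeats <- function(sequence, min_arm, max_spacer) {
  n <- nchar(sequence)
  v <- strsplit(sequence, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cv <- unname(comp[v])
  out <- list()
  for (cc in 3:(2 * n - 1)) {
    lo <- max(1, cc - n)
    hi <- floor((cc - 2) / 2)
    if (hi < lo) next
    m <- v[lo:hi] == cv[cc - (lo:hi)]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$lengths)) {
      if (!r$values[k] || r$lengths[k] < min_arm) next
      L <- lo + starts[k] - 1; R <- lo + ends[k] - 1
      sp <- cc - 2 * R - 1
      if (sp >= 1 && sp <= max_spacer)
        out[[length(out) + 1]] <- data.frame(
          arm1_start = L, arm1_end = R, arm2_start = cc - R,
          arm2_end = cc - L, arm_len = R - L + 1)
    }
  }
  if (length(out) == 0)
    return(data.frame(arm1_start = integer(0), arm1_end = integer(0),
                      arm2_start = integer(0), arm2_end = integer(0),
                      arm_len = integer(0)))
  unique(do.call(rbind, out))
}

# naive sliding-window Hamming alignment oracle
oracle_align <- function(tag, chrom_seq, max_mm) {
  n <- nchar(chrom_seq); w <- nchar(tag)
  tv <- strsplit(tag, "")[[1]]
  rv <- strsplit(srnaqtl::revcomp(tag), "")[[1]]
  gv <- strsplit(chrom_seq, "")[[1]]
  hits <- list()
  for (s in seq_len(n - w + 1)) {
    win <- gv[s:(s + w - 1)]
    mmf <- sum(win != tv)
    if (mmf <= max_mm)
      hits[[length(hits) + 1]] <- data.frame(start = s, end = s + w - 1,
                                             strand = "+", mismatches = mmf)
    mmr <- sum(win != rv)
    if (mmr <= max_mm)
      hits[[length(hits) + 1]] <- data.frame(start = s, end = s + w - 1,
                                             strand = "-", mismatches = mmr)
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  do.call(rbind, hits)
}
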
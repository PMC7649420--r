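# Bin-level QTL scanning: F2 genotype encoding, forward cofactor selection,
# composite-interval-mapping-style LOD profiles from nested least squares,
# QTL calling with LOD-drop support intervals, permutation thresholds, and
# hotspot detection.

#' Encode F2 bin genotypes as additive/dominance design columns
#'
#' P1 -> (-1, 0), HET -> (0, 1), P2 -> (+1, 0).
#'
#' @param genotypes individuals x bins matrix over {"P1","HET","P2"}.
#' @return list: `xa` (additive) and `xd` (dominance) numeric matrices.
#' @export
encode_genotypes <- function(genotypes) {
  xa <- matrix(0, nrow(genotypes), ncol(genotypes),
               dimnames = dimnames(genotypes))
  xa[genotypes == "P1"] <- -1
  xa[genotypes == "P2"] <- 1
  xd <- matrix(0, nrow(genotypes), ncol(genotypes),
               dimnames = dimnames(genotypes))
  xd[genotypes == "HET"] <- 1
  list(xa = xa, xd = xd)
}

rss_fit <- function(X, y) {
  sum(stats::lm.fit(X, y)$residuals^2)
}

drop_const <- function(X) {
  keep <- apply(X, 2, function(c) max(c) > min(c))
  keep[1] <- TRUE   # intercept
  X[, keep, drop = FALSE]
}

#' Forward selection of cofactor bins
#'
#' Repeatedly adds the bin whose additive term most reduces the residual sum
#' of squares, up to `k` bins.
#'
#' @param y trait values.
#' @param xa additive design matrix (individuals x bins).
#' @param k maximum number of cofactors.
#' @return integer vector of selected bin indices (possibly empty).
#' @export
select_cofactors <- function(y, xa, k = 3) {
  if (k == 0) return(integer(0))
  keep <- is.finite(y)
  y <- y[keep]; xa <- xa[keep, , drop = FALSE]
  stopifnot(length(y) > k + 3)
  chosen <- integer(0)
  X <- matrix(1, length(y), 1)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(ncol(xa)), chosen)
    rss <- vapply(cand, function(b) rss_fit(cbind(X, xa[, b]), y), numeric(1))
    best <- cand[which.min(rss)]
    chosen <- c(chosen, best)
    X <- cbind(X, xa[, best])
  }
  chosen
}

active_cofactors <- function(cofactors, b, bin_chrom, window) {
  if (length(cofactors) == 0) return(integer(0))
  drop <- bin_chrom[cofactors] == bin_chrom[b] & abs(cofactors - b) <= window
  cofactors[!drop]
}

#' LOD profile of one trait across bins
#'
#' At each bin the full model is intercept + cofactor additive terms (minus
#' cofactors within `window` bins of the tested bin on its chromosome) + the
#' bin's additive and dominance columns; the reduced model drops the bin's
#' columns. `LOD = (n/2) log10(RSS0 / RSS1)`. Constant design columns (e.g.
#' a bin with no HET individuals) are dropped; LOD is capped when the full
#' model fits exactly.
#'
#' @param y trait values (individuals).
#' @param xa,xd design matrices from [encode_genotypes()].
#' @param bin_chrom chromosome label per bin.
#' @param cofactors cofactor bin indices (see [select_cofactors()]).
#' @param window cofactor exclusion window in bins.
#' @param lod_cap upper bound substituted when RSS1 underflows.
#' @return list of class `lod_profile`: `lod` (per bin), `cofactors`, `n`.
#' @export
scan_trait <- function(y, xa, xd, bin_chrom, cofactors = integer(0),
                       window = 10, lod_cap = 300) {
  keep <- is.finite(y)
  y <- y[keep]
  xa <- xa[keep, , drop = FALSE]; xd <- xd[keep, , drop = FALSE]
  n <- length(y)
  nb <- ncol(xa)
  if (stats::var(y) == 0) {
    warning("zero-variance trait; all-zero LOD profile")
    return(structure(list(lod = rep(0, nb), cofactors = cofactors, n = n),
                     class = "lod_profile"))
  }
  lod <- numeric(nb)
  for (b in seq_len(nb)) {
    ac <- active_cofactors(cofactors, b, bin_chrom, window)
    X0 <- drop_const(cbind(1, xa[, ac, drop = FALSE]))
    X1 <- drop_const(cbind(X0, xa[, b], xd[, b]))
    rss0 <- rss_fit(X0, y)
    rss1 <- rss_fit(X1, y)
    lod[b] <- if (rss1 <= rss0 * 10^(-2 * lod_cap / n) || rss1 <= 0)
      lod_cap else max(0, n / 2 * log10(rss0 / rss1))
  }
  structure(list(lod = lod, cofactors = cofactors, n = n),
            class = "lod_profile")
}

# Vectorized genome-wide max LOD over the columns of Y (n x P), used for
# permutations. Same model as scan_trait.
scan_max_lod <- function(Y, xa, xd, bin_chrom, cofactors = integer(0),
                         window = 10, lod_cap = 300) {
  n <- nrow(Y)
  nb <- ncol(xa)
  yss <- colSums(Y^2)
  maxlod <- rep(0, ncol(Y))
  for (b in seq_len(nb)) {
    ac <- active_cofactors(cofactors, b, bin_chrom, window)
    X0 <- drop_const(cbind(1, xa[, ac, drop = FALSE]))
    X1 <- drop_const(cbind(X0, xa[, b], xd[, b]))
    Q0 <- qr.Q(qr(X0)); Q1 <- qr.Q(qr(X1))
    rss0 <- pmax(yss - colSums(crossprod(Q0, Y)^2), 0)
    rss1 <- pmax(yss - colSums(crossprod(Q1, Y)^2), 0)
    lod <- ifelse(rss1 <= 0, lod_cap,
                  pmin(lod_cap, pmax(0, n / 2 * log10(rss0 / rss1))))
    maxlod <- pmax(maxlod, lod)
  }
  maxlod
}

#' Call QTLs from a LOD profile
#'
#' Local maxima at or above the threshold become calls; the support interval
#' is the contiguous run of bins (within the chromosome) with LOD >=
#' peak - `lod_drop`, and lower peaks inside an accepted support interval are
#' merged into it.
#'
#' @param profile a `lod_profile` (or numeric LOD vector).
#' @param bin_chrom chromosome label per bin.
#' @param lod_threshold minimum peak LOD (a peak of exactly the threshold is
#'   called).
#' @param lod_drop LOD drop defining the support interval.
#' @return data.frame: peak_bin, chrom, lod, support_start, support_end.
#' @export
call_qtls <- function(profile, bin_chrom, lod_threshold = 5,
                      lod_drop = 1.5) {
  lod <- if (inherits(profile, "lod_profile")) profile$lod else profile
  out <- data.frame(peak_bin = integer(0), chrom = character(0),
                    lod = numeric(0), support_start = integer(0),
                    support_end = integer(0))
  n <- length(lod)
  is_peak <- vapply(seq_len(n), function(b) {
    left_ok <- b == 1 || bin_chrom[b - 1] != bin_chrom[b] ||
      lod[b] >= lod[b - 1]
    right_ok <- b == n || bin_chrom[b + 1] != bin_chrom[b] ||
      lod[b] >= lod[b + 1]
    left_ok && right_ok
  }, logical(1))
  cand <- which(lod >= lod_threshold & is_peak)
  while (length(cand)) {
    peak <- cand[which.max(lod[cand])]
    ch <- bin_chrom[peak]
    lo <- peak
    while (lo > 1 && bin_chrom[lo - 1] == ch &&
             lod[lo - 1] >= lod[peak] - lod_drop) lo <- lo - 1
    hi <- peak
    while (hi < length(lod) && bin_chrom[hi + 1] == ch &&
             lod[hi + 1] >= lod[peak] - lod_drop) hi <- hi + 1
    out <- rbind(out, data.frame(peak_bin = peak, chrom = ch,
                                 lod = lod[peak], support_start = lo,
                                 support_end = hi))
    cand <- cand[cand < lo | cand > hi]
  }
  out[order(out$peak_bin), , drop = FALSE]
}

#' Permutation threshold for the genome-wide maximum LOD
#'
#' Trait values are permuted across individuals, the scan is repeated, and
#' the empirical `1 - alpha` quantile of the genome-wide maximum LOD is
#' returned. With cofactors, the cofactor set selected on the observed trait
#' is held fixed across permutations.
#'
#' @param y trait values.
#' @param xa,xd design matrices.
#' @param bin_chrom chromosome label per bin.
#' @param k cofactors selected on the observed trait (0 = plain interval
#'   mapping, under which the permutation test is exactly calibrated).
#' @param window cofactor exclusion window.
#' @param n_perm number of permutations.
#' @param alpha genome-wide type-I error rate.
#' @param seed RNG seed (deterministic threshold per seed).
#' @return list: `threshold`, `max_lods` (per permutation), `cofactors`.
#' @export
permutation_threshold <- function(y, xa, xd, bin_chrom, k = 0, window = 10,
                                  n_perm = 1000, alpha = 0.05, seed = 1) {
  stopifnot(n_perm >= 100)
  keep <- is.finite(y)
  y <- y[keep]
  xa <- xa[keep, , drop = FALSE]; xd <- xd[keep, , drop = FALSE]
  cof <- if (k > 0) select_cofactors(y, xa, k) else integer(0)
  maxl <- local_seed(seed, {
    Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
    scan_max_lod(Y, xa, xd, bin_chrom, cof, window)
  })
  list(threshold = as.numeric(stats::quantile(maxl, 1 - alpha, type = 1)),
       max_lods = maxl, cofactors = cof)
}

#' Detect QTL hotspots
#'
#' A bin qualifies when the number of traits whose QTL peaks there exceeds
#' `max(min_traits, qpois(q, lambda))` with `lambda` the mean per-bin count;
#' consecutive qualifying bins on one chromosome are reported as a single
#' hotspot run.
#'
#' @param peak_bins integer vector of peak bin indices (one entry per QTL
#'   call).
#' @param n_bins total number of bins.
#' @param bin_chrom chromosome label per bin.
#' @param min_traits fixed count floor; default scales with the number of
#'   calls (`ceiling(0.05 * length(peak_bins))`).
#' @param q Poisson quantile used for the count threshold.
#' @return data.frame: hotspot, chrom, bin_start, bin_end, n_traits.
#' @export
detect_hotspots <- function(peak_bins, n_bins, bin_chrom, min_traits = NULL,
                            q = 0.999) {
  empty <- data.frame(hotspot = integer(0), chrom = character(0),
                      bin_start = integer(0), bin_end = integer(0),
                      n_traits = integer(0))
  if (length(peak_bins) == 0) return(empty)
  counts <- tabulate(peak_bins, n_bins)
  lambda <- mean(counts)
  thr <- max(min_traits %||% ceiling(0.05 * length(peak_bins)),
             stats::qpois(q, lambda))
  qual <- counts > thr
  if (!any(qual)) return(empty)
  idx <- which(qual)
  brk <- c(TRUE, diff(idx) != 1 | bin_chrom[idx[-1]] !=
             bin_chrom[idx[-length(idx)]])
  grp <- cumsum(brk)
  do.call(rbind, lapply(split(idx, grp), function(b)
    data.frame(chrom = bin_chrom[b[1]], bin_start = b[1],
               bin_end = b[length(b)], n_traits = sum(counts[b])))) ->
    runs
  runs$hotspot <- seq_len(nrow(runs))
  rownames(runs) <- NULL
  runs[, c("hotspot", "chrom", "bin_start", "bin_end", "n_traits")]
}

#' Scan a set of traits and call their QTLs
#'
#' Convenience wrapper: per trait, select cofactors, scan, and call QTLs.
#'
#' @param values traits x individuals matrix.
#' @param genotypes individuals x bins genotype matrix (or an
#'   `encode_genotypes()` list).
#' @param bin_chrom chromosome label per bin.
#' @param k number of cofactors.
#' @param window cofactor exclusion window (bins).
#' @param lod_threshold,lod_drop see [call_qtls()].
#' @return data.frame of calls with a `trait` column.
#' @export
scan_traits <- function(values, genotypes, bin_chrom, k = 3, window = 10,
                        lod_threshold = 5, lod_drop = 1.5) {
  enc <- if (is.list(genotypes) && !is.null(genotypes$xa)) genotypes
         else encode_genotypes(genotypes)
  calls <- lapply(rownames(values), function(tr) {
    y <- values[tr, ]
    if (stats::var(y, na.rm = TRUE) == 0) return(NULL)
    cof <- select_cofactors(y, enc$xa, k)
    prof <- scan_trait(y, enc$xa, enc$xd, bin_chrom, cof, window)
    cl <- call_qtls(prof, bin_chrom, lod_threshold, lod_drop)
    if (nrow(cl) == 0) return(NULL)
    cl$trait <- tr
    cl
  })
  calls <- do.call(rbind, calls)
  if (is.null(calls))
    return(data.frame(peak_bin = integer(0), chrom = character(0),
                      lod = numeric(0), support_start = integer(0),
                      support_end = integer(0), trait = character(0)))
  calls[, c("trait", "chrom", "peak_bin", "lod", "support_start",
            "support_end")]
}
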
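# Recombination-bin genetic map: collapse ordered markers into bins of SNPs
# with no recombination breakpoint across the RIL population, and deduce IMF2
# genotypes from the RIL cross table.

#' Build a recombination-bin map from RIL marker genotypes
#'
#' Markers are scanned in genomic order per chromosome; a new bin starts
#' whenever any RIL's non-missing genotype conflicts with the running bin
#' consensus, so each bin is a run of markers with no recombination event in
#' any RIL and the boundary between adjacent bins marks a detected
#' recombination. Missing genotypes are imputed from the bin consensus.
#'
#' @param ril_genotypes RILs x markers matrix over {"P1","P2",NA}.
#' @param markers data.frame(marker, chrom, pos) in genomic order.
#' @param chrom_len chromosome length(s) used for the outer bin boundaries
#'   (single value or named per chromosome); defaults to the last marker
#'   position per chromosome.
#' @param min_bin_markers bins with fewer member markers are merged into the
#'   preceding bin (1 = no smoothing).
#' @return list of class `bin_map`: `bins` (bin, chrom, start, end,
#'   first_marker, last_marker, n_markers), `ril_bin_genotypes` (RILs x bins).
#' @export
build_bin_map <- function(ril_genotypes, markers, chrom_len = NULL,
                          min_bin_markers = 1) {
  stopifnot(ncol(ril_genotypes) == nrow(markers))
  if (any(ril_genotypes == "HET", na.rm = TRUE))
    stop("RIL genotypes must be homozygous (P1/P2)")
  bins <- list(); geno_cols <- list()
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    idx <- idx[order(markers$pos[idx])]
    runs <- list(); cons <- NULL; run <- integer(0)
    flush <- function() {
      if (length(run)) runs[[length(runs) + 1]] <<- list(idx = run,
                                                         cons = cons)
    }
    for (i in idx) {
      g <- ril_genotypes[, i]
      if (is.null(cons)) { cons <- g; run <- i; next }
      conflict <- !is.na(cons) & !is.na(g) & cons != g
      if (any(conflict)) {
        flush()
        cons <- g; run <- i
      } else {
        cons[is.na(cons)] <- g[is.na(cons)]
        run <- c(run, i)
      }
    }
    flush()
    # smoothing: merge short bins into the previous one (consensus of the
    # longer run wins at conflicting RILs)
    if (min_bin_markers > 1 && length(runs) > 1) {
      merged <- list(runs[[1]])
      for (r in runs[-1]) {
        if (length(r$idx) < min_bin_markers) {
          last <- merged[[length(merged)]]
          last$idx <- c(last$idx, r$idx)
          miss <- is.na(last$cons)
          last$cons[miss] <- r$cons[miss]
          merged[[length(merged)]] <- last
        } else merged[[length(merged) + 1]] <- r
      }
      runs <- merged
    }
    pos <- markers$pos
    cl <- if (is.null(chrom_len)) max(pos[idx]) else
      if (length(chrom_len) == 1 && is.null(names(chrom_len))) chrom_len else
        chrom_len[[ch]]
    for (k in seq_along(runs)) {
      r <- runs[[k]]
      start <- if (k == 1) 1L else
        floor((pos[r$idx[1]] + pos[runs[[k - 1]]$idx[length(
          runs[[k - 1]]$idx)]]) / 2) + 1L
      end <- if (k == length(runs)) as.integer(cl) else
        floor((pos[r$idx[length(r$idx)]] + pos[runs[[k + 1]]$idx[1]]) / 2)
      cons <- r$cons
      cons[is.na(cons)] <- "P1"   # all-missing across the bin: arbitrary fill
      bins[[length(bins) + 1]] <- data.frame(
        chrom = ch, start = start, end = end,
        first_marker = markers$marker[r$idx[1]],
        last_marker = markers$marker[r$idx[length(r$idx)]],
        n_markers = length(r$idx))
      geno_cols[[length(geno_cols) + 1]] <- cons
    }
  }
  bins <- do.call(rbind, bins)
  bins$bin <- seq_len(nrow(bins))
  bins <- bins[, c("bin", "chrom", "start", "end", "first_marker",
                   "last_marker", "n_markers")]
  geno <- do.call(cbind, geno_cols)
  dimnames(geno) <- list(rownames(ril_genotypes),
                         paste0("bin", bins$bin))
  structure(list(bins = bins, ril_bin_genotypes = geno), class = "bin_map")
}

#' Expand bin genotypes back to marker resolution
#'
#' @param binmap a `bin_map`.
#' @param markers the marker table used to build it.
#' @return RILs x markers matrix of bin-consensus genotypes.
#' @export
expand_bin_genotypes <- function(binmap, markers) {
  out <- matrix(NA_character_, nrow(binmap$ril_bin_genotypes), nrow(markers),
                dimnames = list(rownames(binmap$ril_bin_genotypes),
                                paste0("m", markers$marker)))
  for (b in seq_len(nrow(binmap$bins))) {
    mk <- which(markers$marker >= binmap$bins$first_marker[b] &
                  markers$marker <= binmap$bins$last_marker[b] &
                  markers$chrom == binmap$bins$chrom[b])
    out[, mk] <- binmap$ril_bin_genotypes[, b]
  }
  out
}

#' Deduce IMF2 bin genotypes from the RIL cross table
#'
#' The IMF2 genotype at a bin is P1 when both crossed RILs are P1, P2 when
#' both are P2, and HET when they differ.
#'
#' @param binmap a `bin_map`.
#' @param cross_table data.frame(imf2, ril1, ril2); RIL ids must match the
#'   rownames of the bin genotype matrix.
#' @return IMF2 x bins matrix over {"P1","P2","HET"}.
#' @export
deduce_imf2_genotypes <- function(binmap, cross_table) {
  g <- binmap$ril_bin_genotypes
  missing_rils <- setdiff(unique(c(cross_table$ril1, cross_table$ril2)),
                          rownames(g))
  if (length(missing_rils))
    stop("unknown RIL id(s): ", paste(missing_rils, collapse = ", "))
  g1 <- g[cross_table$ril1, , drop = FALSE]
  g2 <- g[cross_table$ril2, , drop = FALSE]
  out <- ifelse(g1 == g2, g1, "HET")
  rownames(out) <- cross_table$imf2
  out
}

#' IMF2 bin genotypes directly from IMF2 marker genotypes
#'
#' Convenience for simulated data where per-marker IMF2 genotypes exist:
#' takes the genotype at each bin's first member marker (constant across the
#' bin by construction of the map).
#'
#' @param binmap a `bin_map`.
#' @param imf2_marker_genotypes IMF2 x markers matrix.
#' @return IMF2 x bins matrix.
#' @export
imf2_bins_from_markers <- function(binmap, imf2_marker_genotypes) {
  cols <- paste0("m", binmap$bins$first_marker)
  out <- imf2_marker_genotypes[, cols, drop = FALSE]
  colnames(out) <- paste0("bin", binmap$bins$bin)
  out
}
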
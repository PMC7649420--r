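#!/usr/bin/env Rscript
# Build the recombination-bin map from RIL genotypes, deduce IMF2 genotypes
# from the cross table, LOD-scan every s-trait and sc-trait with cofactors,
# and call QTLs (LOD >= 5). Writes results/qtl/.

library(srnaqtl)

sim <- readRDS("results/scenario.rds")
tr <- readRDS("results/traits.rds")
out <- "results/qtl"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

bm <- build_bin_map(sim$pop$ril_genotypes, sim$pop$markers,
                    chrom_len = sim$genomes$design$chrom_len)
cat("Bin map:", nrow(bm$bins), "bins from",
    nrow(sim$pop$markers), "markers\n")
ib <- deduce_imf2_genotypes(bm, sim$pop$cross_table)

s_calls <- scan_traits(tr$straits$values, ib, bm$bins$chrom, k = 3)
cat("sQTLs:", nrow(s_calls), "calls for",
    length(unique(s_calls$trait)), "s-traits\n")
sc_calls <- if (nrow(tr$sctraits$values))
  scan_traits(tr$sctraits$values, ib, bm$bins$chrom, k = 3) else NULL
if (!is.null(sc_calls))
  cat("scQTLs:", nrow(sc_calls), "calls for",
      length(unique(sc_calls$trait)), "sc-traits\n")

write.table(bm$bins, file.path(out, "bin_map.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(s_calls, file.path(out, "s_qtls_unresolved.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(list(binmap = bm, imf2_bins = ib, s_calls = s_calls,
             sc_calls = sc_calls), "results/scan.rds")
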
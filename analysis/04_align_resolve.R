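#!/usr/bin/env Rscript
# Align trait sequences to both parental genomes, resolve each QTL as local
# or distant, authenticate multi-mapped alignments near local QTLs, and call
# QTL hotspots. Writes results/qtl/ tables.

library(srnaqtl)

sim <- readRDS("results/scenario.rds")
tr <- readRDS("results/traits.rds")
sc <- readRDS("results/scan.rds")
out <- "results/qtl"

traits <- unique(sc$s_calls$trait)
hits <- align_tags(setNames(traits, traits), sim$genomes)
cat("Alignments:", nrow(hits), "hits for", length(unique(hits$query)),
    "of", length(traits), "s-traits with QTLs\n")

s_calls <- resolve_local_distant(sc$s_calls, hits, sc$binmap)
cat("Resolution:\n"); print(table(s_calls$mode))

hot <- detect_hotspots(s_calls$peak_bin, nrow(sc$binmap$bins),
                       sc$binmap$bins$chrom)
cat("Hotspots:\n"); print(hot)

# authentic alignments for multi-mapped traits with local QTLs
multi <- names(which(table(hits$query) > 1))
auth <- do.call(rbind, lapply(multi, function(q) {
  ql <- s_calls[s_calls$trait == q, , drop = FALSE]
  if (!any(ql$mode == "local")) return(NULL)
  a <- authenticate_alignments(hits[hits$query == q, ], ql, sc$binmap)
  if (nrow(a)) a else NULL
}))
cat("Authentic alignments retained for",
    length(unique(auth$query)), "of", length(multi),
    "multi-mapped traits (", nrow(auth), "of",
    sum(hits$query %in% multi), "alignments )\n")

write.table(s_calls, file.path(out, "s_qtls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(hot, file.path(out, "s_hotspots.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
if (!is.null(auth))
  write.table(auth, file.path(out, "authentic_alignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(list(s_calls = s_calls, hotspots = hot, hits = hits, auth = auth),
        "results/resolve.rds")
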
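#!/usr/bin/env Rscript
# Quantify expression without a reference genome: collapse reads to unique
# tags, RPM-normalize, define s-traits; assemble reads into clusters, count
# with unique placement, size-factor-normalize, define sc-traits.
# Reads results/scenario.rds; writes trait tables under results/traits/.

library(srnaqtl)

sim <- readRDS("results/scenario.rds")
out <- "results/traits"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

tags <- collapse_reads(sim$srna$libraries)
cat("Collapsed", nrow(tags$counts), "unique tags from",
    ncol(tags$counts), "libraries\n")

rpm <- rpm_normalize(tags)
straits <- define_s_traits(rpm, tags$counts)
cat("s-traits:", straits$n_retained, "of", straits$n_total,
    "tags present in >", straits$presence_min, "individuals\n")

comp <- composition_traits(tags)
write.table(cbind(trait = rownames(comp$values),
                  as.data.frame(comp$values)),
            file.path(out, "composition_traits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

pooled <- setNames(rowSums(tags$counts), rownames(tags$counts))
contigs <- assemble_clusters(pooled)
clusters <- filter_contigs(merge_contigs(unique(contigs$sequence)), 60)
cat("Assembly:", nrow(contigs), "contigs ->", nrow(clusters),
    "clusters >= 60 bp (lengths:",
    paste(range(clusters$length), collapse = "-"), "bp)\n")

cc <- count_cluster_reads(tags, clusters)
sf <- size_factors(cc$counts, fallback = TRUE)
cnorm <- normalize_counts(cc$counts, sf)
sctraits <- define_sc_traits(cnorm)
cat("sc-traits:", sctraits$n_retained, "of", nrow(clusters), "clusters\n")

write.table(cbind(trait = rownames(straits$values),
                  as.data.frame(straits$values)),
            file.path(out, "s_traits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(clusters[, c("id", "sequence", "length")],
            file.path(out, "clusters.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(library = names(sf), size_factor = sf),
            file.path(out, "size_factors.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(list(tags = tags, straits = straits, clusters = clusters,
             cluster_counts = cc, sctraits = sctraits),
        "results/traits.rds")
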
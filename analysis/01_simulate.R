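#!/usr/bin/env Rscript
# Simulate the synthetic biparental IMF2 study: two parental genomes with
# planted LIR variation, 200 RILs, 98 IMF2s from paired crosses, sRNA and
# mRNA libraries, and the truth table of planted effects.
# Writes genomes, genotypes and library summaries under results/simulation/.

library(srnaqtl)

seed <- 1
out <- "results/simulation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- population_design(seed = seed)
sim <- simulate_scenario(design)

write_genome_fasta(sim$genomes, out)
write.table(sim$genomes$manifest, file.path(out, "genome_manifest.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(id = rownames(sim$pop$ril_genotypes),
                  as.data.frame(sim$pop$ril_genotypes)),
            file.path(out, "ril_genotypes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$pop$cross_table, file.path(out, "cross_table.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$truth$planted_qtls,
            file.path(out, "truth_planted_qtls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
# one example collapsed sRNA library on disk; the rest live in memory
write_collapsed_fasta(sim$srna$libraries[[1]],
                      file.path(out, "IMF2_1.collapsed.fa"))

cat("Simulated", design$n_ril, "RILs,", design$n_imf2, "IMF2s,",
    nrow(sim$truth$tags), "trait tags across",
    nrow(sim$truth$planted_qtls), "planted effect sets\n")
cat("Planted effects:\n")
print(sim$truth$planted_qtls)
saveRDS(sim, file.path("results", "scenario.rds"))  # consumed by later steps
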
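#!/usr/bin/env Rscript
# Long-inverted-repeat dissection of local-QTL hotspots: detect LIRs in both
# parental genomes, classify structural differences, quantify LIR expression
# from mRNA reads per genotype, test genotype association, and correlate
# sRNA with LIR expression. Writes results/lir/.

library(srnaqtl)

sim <- readRDS("results/scenario.rds")
tr <- readRDS("results/traits.rds")
sc <- readRDS("results/scan.rds")
out <- "results/lir"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

l1 <- find_inverted_repeats(unlist(sim$genomes$genomes$P1))
l2 <- find_inverted_repeats(unlist(sim$genomes$genomes$P2))
cat("LIR records: parent1", nrow(l1), ", parent2", nrow(l2), "\n")

loci <- srnaqtl:::derive_lir_loci(l1, l2)
cls <- suppressWarnings(compare_lir_across_genomes(l1, l2, loci, sim$genomes))
print(cls)

rpm <- rpm_normalize(tr$tags)
assoc <- list()
for (i in seq_len(nrow(loci))) {
  w <- loci[i, ]
  mid <- (w$start + w$end) %/% 2
  b <- sc$binmap$bins[sc$binmap$bins$chrom == w$chrom &
                        sc$binmap$bins$start <= mid &
                        sc$binmap$bins$end >= mid, ]
  geno <- sc$imf2_bins[, paste0("bin", b$bin[1])]
  ref_of <- function(recs, parent) {
    r <- recs[!is.na(recs$chrom) & recs$chrom == w$chrom &
                recs$arm1_start <= w$end & recs$arm2_end >= w$start, ]
    if (nrow(r) == 0) return(NULL)
    r <- r[which.max(r$arm_len), ]
    substring(sim$genomes$genomes[[parent]][[w$chrom]], r$arm1_start,
              r$arm2_end)
  }
  expr <- quantify_lir_expression(
    sim$mrna$libraries, list(P1 = ref_of(l1, "P1"), P2 = ref_of(l2, "P2")),
    geno)
  a <- associate_expression_genotype(expr, geno)
  cat("\n", w$name, "(bin", b$bin[1], ") LIR expression by genotype:\n")
  print(a$summary); print(a$tests)
  # sRNA traits whose QTL peaks at this bin: correlation with LIR expression
  reg <- sc$s_calls$trait[abs(sc$s_calls$peak_bin - b$bin[1]) <= 1]
  reg <- intersect(reg, rownames(rpm))
  if (length(reg) >= 3) {
    r <- correlate_srna_lir(rpm[reg, , drop = FALSE], expr)
    cat("sRNA-LIR correlations:", length(reg), "traits;",
        round(100 * mean(r > 0, na.rm = TRUE), 1), "% positive\n")
  }
  assoc[[w$name]] <- list(expr = expr, genotypes = geno, tests = a$tests)
}

write.table(cls, file.path(out, "lir_classes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rbind(transform(l1, parent = "P1"),
                  transform(l2, parent = "P2")),
            file.path(out, "lir_records.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(assoc, "results/lir.rds")
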
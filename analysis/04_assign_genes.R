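#!/usr/bin/env Rscript
# Stage 4: variant-to-gene assignment. Every scanned variant is mapped
# to the gene whose body lies within 1 kb, with the feature-priority rule
# exon > UTR > intron > flank deciding between overlapping genes, and
# candidates are grouped at the p < 1e-4 cutoff.

suppressMessages(library(modscreen))

dir.create("results/genes", showWarnings = FALSE, recursive = TRUE)

assoc <- read_assoc_results("results/gwas/assoc.tsv")
annot <- read_annotation("results/panel/genes.gff3")

assignments <- assign_variants(assoc, annot)
write.table(assignments, "results/genes/assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("variant context of the scan:\n")
print(table(assignments$category))

cands <- candidate_genes(assignments, assoc, p_cutoff = 1e-4)
write.table(cands$genes, "results/genes/candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- jsonlite::read_json("results/panel/truth.json",
                             simplifyVector = TRUE)
sets <- read_gene_sets("results/panel/sets.gmt")
planted_genes <- sets[[truth$planted_set_id]]
cat(sprintf("\n%d candidate genes at p < 1e-4 (%d intergenic hits set aside)\n",
            nrow(cands$genes), nrow(cands$intergenic)))
cat(sprintf("%d/%d candidates belong to the planted pathway\n",
            sum(cands$genes$gene_id %in% planted_genes),
            nrow(cands$genes)))
print(cands$genes[, c("gene_id", "n_variants", "min_p")],
      row.names = FALSE)
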
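#!/usr/bin/env Rscript
# Stage 1: build the synthetic mapping panel that the rest of the
# analysis runs on, and leave every input behind in standard formats.
#
# The panel emulates a DGRP-style screen: 200 fully homozygous lines in
# 20 relatedness blocks, 5000 common variants (MAF >= 0.05) on a 3 Mb
# chromosome carrying 300 gene models, 50 gene sets, and per-individual
# eye-area phenotypes (10-15 females per line, SD ~400 px) whose 20
# causal variants all sit within 1 kb of genes in one planted set.

suppressMessages(library(modscreen))

out <- "results/panel"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1L)
geno <- simulate_genotypes(cfg)
annot <- simulate_annotation(cfg$n_genes, cfg$chrom_length, seed = cfg$seed)
sets <- simulate_gene_sets(annot$genes$gene_id, cfg$n_sets,
                           cfg$set_size_range, seed = cfg$seed)
sim <- simulate_phenotypes(geno, annot, sets, cfg)

write_genotypes(geno, file.path(out, "panel.vcf"))
write_annotation(annot, file.path(out, "genes.gff3"))
write_gene_sets(sets, file.path(out, "sets.gmt"))
write_phenotypes(sim$phenotypes, file.path(out, "phenotypes.csv"))
jsonlite::write_json(
  sim$truth[c("causal_variant_ids", "causal_betas", "planted_set_id")],
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

af <- colMeans(geno$geno, na.rm = TRUE) / 2
cat(sprintf("panel: %d lines x %d variants, %.1f%% missing calls\n",
            n_lines(geno), n_variants(geno),
            100 * mean(is.na(geno$geno))))
cat(sprintf("mean realized MAF %.3f (target midpoint %.3f)\n",
            mean(pmin(af, 1 - af)), mean(cfg$maf_range)))
cat(sprintf("%d causal variants planted in set '%s' (|beta| = %g px)\n",
            length(sim$truth$causal_variant_ids), cfg$planted_set_id,
            cfg$causal_effect_size))
cat(sprintf("%d individuals phenotyped across %d lines\n",
            nrow(sim$phenotypes), length(unique(sim$phenotypes$line_id))))
cat("inputs written under", out, "\n")
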
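#!/usr/bin/env Rscript
# Stage 6: knockdown validation statistics. Emulates an RNAi follow-up
# of the top candidate genes: each knockdown group (11-15 flies) is
# compared with its genetically matched control using Dunnett's
# many-to-one test. Two candidates are simulated as true enhancers
# (smaller eyes), two as suppressors, and the rest as nulls, so the
# test's calls can be checked against the design.

suppressMessages(library(modscreen))

dir.create("results/validation", showWarnings = FALSE, recursive = TRUE)

cands <- read.delim("results/genes/candidates.tsv")
k <- min(8, nrow(cands))
genes <- cands$gene_id[seq_len(k)]
effects <- rep(0, k)
effects[seq_len(min(2, k))] <- -1600                 # enhancers
if (k >= 4) effects[3:4] <- c(1400, 1200)            # suppressors
names(effects) <- genes

tab <- simulate_rnai_experiment(control_mean = 17500, control_sd = 900,
                                effects = effects, n_per_group = 13,
                                seed = 99)
write_phenotypes(tab, "results/validation/rnai_phenotypes.csv")

dn <- dunnett_test(tab, control_id = "control", alpha = 0.05, seed = 7)
write.table(dn, "results/validation/dunnett.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("Dunnett many-to-one test: %d knockdowns vs shared control\n",
            nrow(dn)))
print(dn, row.names = FALSE)
truth_dir <- ifelse(effects < 0, "enhancer",
                    ifelse(effects > 0, "suppressor", "ns"))
cat(sprintf("calls matching the simulated design: %d/%d\n",
            sum(dn$direction == truth_dir[dn$group_id]), nrow(dn)))
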
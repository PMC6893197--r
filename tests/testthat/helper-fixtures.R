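# Small fixtures built in code; every test that needs randomness draws
# through a fixed seed so the suite is reproducible.

# tiny panel with fully known genotypes
tiny_panel <- function(geno_mat, chrom = "2R", pos = NULL) {
  p <- ncol(geno_mat)
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = p)
  panel_genotypes(
    line_ids = sprintf("L%02d", seq_len(nrow(geno_mat))),
    variants = data.frame(variant_id = sprintf("v%03d", seq_len(p)),
                          chrom = chrom, pos = pos,
                          ref = "A", alt = "T",
                          stringsAsFactors = FALSE),
    geno = geno_mat)
}

small_cfg <- function(...) {
  args <- list(n_lines = 50L, n_variants = 400L, n_blocks = 5L,
               n_genes = 60L, chrom_length = 6e5, n_sets = 10L,
               n_causal = 5L, seed = 101L)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# one simulated screen input bundle (genotypes, annotation, sets, phenos)
sim_bundle <- function(cfg = small_cfg()) {
  geno <- simulate_genotypes(cfg)
  annot <- simulate_annotation(cfg$n_genes, cfg$chrom_length,
                               seed = cfg$seed)
  sets <- simulate_gene_sets(annot$genes$gene_id, cfg$n_sets,
                             cfg$set_size_range,
                             planted_set_id = cfg$planted_set_id,
                             seed = cfg$seed)
  ph <- simulate_phenotypes(geno, annot, sets, cfg)
  list(cfg = cfg, geno = geno, annot = annot, sets = sets,
       pheno = ph$phenotypes, truth = ph$truth)
}

# a simple three-gene annotation with hand-placed features, used by the
# assignment tests: coordinates chosen so every category is reachable
hand_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = "2R",
    start = c(10000L, 14000L, 30000L),
    end = c(12000L, 16000L, 33000L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB", "gC"),
    start = c(10000L, 11500L, 14000L, 30000L),
    end = c(10500L, 12000L, 16000L, 33000L))
  utrs <- data.frame(
    gene_id = c("gA", "gC"),
    start = c(10000L, 32800L),
    end = c(10150L, 33000L),
    side = c("five_prime", "three_prime"))
  gene_annotation(genes, exons, utrs)
}

# independent per-base classification oracle: for one gene, scan every
# base of a window and classify by direct interval membership
oracle_classify <- function(pos, gene, exons, utrs, window = 1000) {
  if (pos >= gene$start && pos <= gene$end) {
    in_utr <- nrow(utrs) && any(pos >= utrs$start & pos <= utrs$end)
    if (in_utr) return("UTR")
    if (any(pos >= exons$start & pos <= exons$end)) return("exon")
    return("intron")
  }
  left <- pos < gene$start && pos >= gene$start - window
  right <- pos > gene$end && pos <= gene$end + window
  if (!left && !right) return("none")
  if (gene$strand == "+") {
    if (left) "upstream" else "downstream"
  } else {
    if (left) "downstream" else "upstream"
  }
}
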
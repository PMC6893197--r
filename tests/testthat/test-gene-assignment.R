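# Window-based variant-to-gene assignment: category logic against a
# per-base oracle, the priority/tie-break rules, and candidate grouping.

test_that("categories follow the declared feature logic", {
  an <- hand_annotation()
  # inside an exon of gA but outside its UTR
  expect_equal(classify_variant("2R", 10300, "gA", an), "exon")
  # inside the 5' UTR (UTR outranks exon at the same base)
  expect_equal(classify_variant("2R", 10100, "gA", an), "UTR")
  # between gA's exons
  expect_equal(classify_variant("2R", 11000, "gA", an), "intron")
  # boundary: exactly 1000 bp 5' of gA is upstream, 1001 bp is none
  expect_equal(classify_variant("2R", 10000 - 1000, "gA", an), "upstream")
  expect_equal(classify_variant("2R", 10000 - 1001, "gA", an), "none")
  # strand flips the flank labels: gB is on '-'
  expect_equal(classify_variant("2R", 13500, "gB", an), "downstream")
  expect_equal(classify_variant("2R", 16500, "gB", an), "upstream")
  expect_equal(classify_variant("3L", 10300, "gA", an), "none")
})

test_that("10000 random positions match a per-base brute-force oracle", {
  an <- simulate_annotation(40, 5e5, seed = 21)
  set.seed(99)
  positions <- sample.int(5e5, 10000)
  for (gid in an$genes$gene_id[c(1, 2, 3, 20, 40)]) {
    g <- an$genes[an$genes$gene_id == gid, ]
    ex <- an$exons[an$exons$gene_id == gid, , drop = FALSE]
    ut <- an$utrs[an$utrs$gene_id == gid, , drop = FALSE]
    got <- vapply(positions, function(p)
      classify_variant("2R", p, gid, an), "")
    want <- vapply(positions, function(p)
      oracle_classify(p, g, ex, ut), "")
    expect_identical(got, want)
  }
})

test_that("assignment picks the highest-priority gene with declared tie-breaks", {
  # overlapping genes: variant in an exon of gA and an intron of gOver
  genes <- data.frame(gene_id = c("gA", "gOver"), chrom = "2R",
                      start = c(1000L, 500L), end = c(2000L, 3000L),
                      strand = "+", stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = c("gA", "gOver", "gOver"),
                      start = c(1000L, 500L, 2500L),
                      end = c(2000L, 700L, 3000L))
  an <- gene_annotation(genes, exons)
  res <- assign_variant("2R", 1500, "v1", an)
  expect_equal(res$gene_id, "gA")
  expect_equal(res$category, "exon")
  expect_equal(res$distance_bp, 0)

  # flank tier tie: 300 bp downstream of gL beats 900 bp upstream of gR
  genes2 <- data.frame(gene_id = c("gL", "gR"), chrom = "2R",
                       start = c(1000L, 3200L), end = c(2000L, 4000L),
                       strand = "+", stringsAsFactors = FALSE)
  exons2 <- data.frame(gene_id = c("gL", "gR"), start = c(1000L, 3200L),
                       end = c(2000L, 4000L))
  an2 <- gene_annotation(genes2, exons2)
  res2 <- assign_variant("2R", 2300, "v2", an2)
  expect_equal(res2$gene_id, "gL")
  expect_equal(res2$category, "downstream")
  expect_equal(res2$distance_bp, 300)

  # equal distance resolves lexicographically
  res3 <- assign_variant("2R", 2600, "v3", an2)
  expect_equal(res3$distance_bp, 600)
  expect_equal(res3$gene_id, "gL")

  # nothing within 1 kb => intergenic
  res4 <- assign_variant("2R", 9000, "v4", an2)
  expect_equal(res4$gene_id, "INTERGENIC")
  expect_equal(res4$category, "intergenic")
})

test_that("assignment equals exhaustive enumeration and ignores gene order", {
  an <- simulate_annotation(30, 4e5, seed = 13)
  set.seed(17)
  positions <- sample.int(4e5, 400)
  prio <- c(exon = 4, UTR = 3, intron = 2, upstream = 1, downstream = 1)
  for (p in positions) {
    got <- assign_variant("2R", p, "v", an)
    # brute force over every (gene, category) pair
    cats <- vapply(an$genes$gene_id, function(gid)
      classify_variant("2R", p, gid, an), "")
    cand <- names(cats)[cats != "none"]
    if (!length(cand)) {
      expect_equal(got$gene_id, "INTERGENIC")
    } else {
      d <- vapply(cand, function(gid) {
        g <- an$genes[an$genes$gene_id == gid, ]
        max(0, max(g$start - p, p - g$end))
      }, numeric(1))
      best <- cand[order(-prio[cats[cand]], d, cand)][1]
      expect_equal(got$gene_id, best)
    }
  }
  # gene input order cannot matter
  an_rev <- gene_annotation(an$genes[rev(seq_len(nrow(an$genes))), ],
                            an$exons, an$utrs)
  a1 <- assign_variants(data.frame(variant_id = sprintf("v%d", positions),
                                   chrom = "2R", pos = positions), an)
  a2 <- assign_variants(data.frame(variant_id = sprintf("v%d", positions),
                                   chrom = "2R", pos = positions), an_rev)
  expect_identical(a1, a2)
  # every variant gets exactly one assignment
  expect_equal(nrow(a1), length(positions))
})

test_that("candidate genes group sub-threshold variants with strict cutoff", {
  an <- hand_annotation()
  v <- data.frame(variant_id = sprintf("v%02d", 1:12), chrom = "2R",
                  pos = c(seq(10600, 11400, length.out = 9),
                          15000, 40000, 41000),
                  stringsAsFactors = FALSE)
  asg <- assign_variants(v, an)
  assoc <- data.frame(variant_id = v$variant_id,
                      p_wald = c(rep(1e-5, 9), 1e-4, 2e-6, 0.5))
  out <- candidate_genes(asg, assoc, p_cutoff = 1e-4)
  # nine intronic hits collapse onto one candidate gene
  gA <- out$genes[out$genes$gene_id == "gA", ]
  expect_equal(gA$n_variants, 9L)
  expect_equal(gA$min_p, 1e-5)
  # p exactly equal to the cutoff is excluded (strict '<')
  expect_false("gB" %in% out$genes$gene_id)
  # intergenic hits are reported separately
  expect_equal(out$intergenic$variant_id, "v11")
  # no variant below cutoff => empty list
  none <- candidate_genes(asg, transform(assoc, p_wald = 0.9))
  expect_equal(nrow(none$genes), 0L)
  expect_error(candidate_genes(asg, assoc, p_cutoff = 1.5), "p_cutoff")
})

test_that("the planted causal gene set is recovered among candidates", {
  hits <- vapply(1:20, function(s) {
    b <- sim_bundle(sim_config(n_lines = 120L, n_variants = 1500L,
                               n_blocks = 12L, n_genes = 120L,
                               chrom_length = 1.2e6, n_sets = 15L,
                               n_causal = 10L, causal_effect_size = 400,
                               seed = 900L + s))
    s_tab <- summarize_strains(b$pheno)
    fg <- suppressMessages(filter_variants(b$geno))
    a <- run_gwas(s_tab, fg)
    asg <- assign_variants(a, b$annot)
    cand <- candidate_genes(asg, a)$genes$gene_id
    any(cand %in% b$sets[[b$cfg$planted_set_id]])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
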
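# Synthetic panel generator: determinism, allele-frequency calibration,
# block relatedness, annotation geometry, gene-set sampling and the
# phenotype model with planted causal structure.

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_lines = 1), "n_lines")
  expect_error(sim_config(maf_range = c(0.2, 0.6)), "maf_range")
  expect_error(sim_config(maf_range = c(0.4, 0.1)), "maf_range")
  expect_error(sim_config(lambda_true = -1), "lambda_true")
  expect_error(sim_config(tau_inv = 0), "tau_inv")
  expect_error(simulate_annotation(0, 1e5), "n_genes")
  expect_error(simulate_annotation(500, 1e4), "chrom_length")
  expect_error(simulate_gene_sets(letters[1:5], 3, size_range = c(8, 10)),
               "set size")
  expect_error(simulate_rnai_experiment(100, -1, c(a = 0), 10), "sd")
  expect_error(simulate_rnai_experiment(100, 1, c(a = 0), 1),
               "n_per_group")
})

test_that("genotypes are homozygous, respect missing_rate and are seeded", {
  cfg <- small_cfg(missing_rate = 0)
  g <- simulate_genotypes(cfg)
  expect_equal(sum(is.na(g$geno)), 0)
  expect_true(all(g$geno %in% c(0, 2)))
  # realized MAF is a minor frequency by definition
  af <- colMeans(g$geno) / 2
  expect_true(all(pmin(af, 1 - af) <= 0.5))
  # bit-identical reruns under the same config
  g2 <- simulate_genotypes(cfg)
  expect_identical(g, g2)
  cfg3 <- small_cfg(missing_rate = 0.1)
  g3 <- simulate_genotypes(cfg3)
  expect_gt(sum(is.na(g3$geno)), 0)
})

test_that("mean realized MAF over 10000 variants sits at the maf_range midpoint", {
  cfg <- sim_config(n_variants = 10000L, seed = 42L)
  g <- simulate_genotypes(cfg)
  af <- colMeans(g$geno, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  expect_lt(abs(mean(maf) - mean(cfg$maf_range)), 0.01)
})

test_that("relatedness blocks share more alleles within than between", {
  cfg <- small_cfg(n_blocks = 2L, n_variants = 800L, missing_rate = 0)
  g <- simulate_genotypes(cfg)
  blocks <- attr(g, "blocks")
  # oracle: compute K directly from the GRM formula, compare group means
  X <- g$geno
  Xc <- sweep(X, 2, colMeans(X))
  K <- tcrossprod(Xc) / ncol(X)
  off <- !diag(TRUE, nrow(K))
  same <- outer(blocks, blocks, `==`) & off
  expect_gt(mean(K[same]), mean(K[!same & off]))
})

test_that("simulated annotation is geometrically sound", {
  an <- simulate_annotation(1, 1e5, seed = 3)
  expect_equal(nrow(an$genes), 1)
  ex <- an$exons
  expect_true(all(ex$start >= an$genes$start & ex$end <= an$genes$end))

  an50 <- simulate_annotation(50, 1e6, seed = 9)
  # brute-force bounds scan over every feature interval
  feats <- rbind(an50$genes[, c("start", "end")],
                 an50$exons[, c("start", "end")],
                 an50$utrs[, c("start", "end")])
  expect_true(all(feats$start >= 1 & feats$end <= 1e6))
  expect_true(all(feats$start <= feats$end))
  # every gene has at least one exon and UTRs nest in exons
  expect_true(all(an50$genes$gene_id %in% an50$exons$gene_id))
  for (i in seq_len(nrow(an50$utrs))) {
    u <- an50$utrs[i, ]
    ex <- an50$exons[an50$exons$gene_id == u$gene_id, ]
    expect_true(any(u$start >= ex$start & u$end <= ex$end))
  }
  # deliberate edge cases: a close gene pair and a wide desert
  gaps <- an50$genes$start[-1] - an50$genes$end[-nrow(an50$genes)] - 1L
  expect_true(any(gaps < 2000))
  expect_true(any(gaps >= 4000))
  # same seed => byte-identical GFF3
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  write_annotation(simulate_annotation(20, 5e5, seed = 11), f1)
  write_annotation(simulate_annotation(20, 5e5, seed = 11), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("gene sets sample without replacement within declared sizes", {
  genes <- sprintf("g%03d", 1:100)
  one <- simulate_gene_sets(genes, 1, size_range = c(100, 100), seed = 1)
  expect_setequal(one[[1]], genes)
  many <- simulate_gene_sets(genes, 40, size_range = c(4, 50), seed = 2)
  sizes <- lengths(many)
  expect_true(all(sizes >= 4 & sizes <= 50))
  expect_true(all(vapply(many, anyDuplicated, 1L) == 0))
})

test_that("overlap of two random size-10 sets from 100 genes matches the hypergeometric mean", {
  genes <- sprintf("g%03d", 1:100)
  ov <- vapply(1:1000, function(s) {
    two <- simulate_gene_sets(genes, 2, size_range = c(10, 10), seed = s)
    length(intersect(two[[1]], two[[2]]))
  }, numeric(1))
  # E[overlap] = 10 * 10 / 100 = 1; MC se ~ 0.03
  expect_lt(abs(mean(ov) - 1), 0.1)
})

test_that("phenotypes follow the planted generative model", {
  # no genetics, no noise => observations equal the baseline exactly
  cfg0 <- small_cfg(n_causal = 0L, lambda_true = 0, replicate_sd = 0)
  b <- sim_bundle(cfg0)
  expect_equal(unique(b$pheno$eye_area_px), cfg0$baseline_px)
  expect_true(all(table(b$pheno$line_id) >= cfg0$n_replicates_range[1]))
  expect_true(all(table(b$pheno$line_id) <= cfg0$n_replicates_range[2]))

  # one strong causal variant, no noise => genotype-class means differ by
  # exactly 2 * beta (0/2 coding)
  cfg1 <- small_cfg(n_causal = 1L, lambda_true = 0, replicate_sd = 0,
                    causal_effect_size = 500, missing_rate = 0)
  b1 <- sim_bundle(cfg1)
  s <- summarize_strains(b1$pheno)
  x <- b1$geno$geno[, b1$truth$causal_variant_ids]
  x <- setNames(x, b1$geno$line_ids)[s$line_id]
  gap <- abs(mean(s$mean_px[x == 2]) - mean(s$mean_px[x == 0]))
  expect_equal(gap, 2 * abs(b1$truth$causal_betas), tolerance = 1e-12)

  # ground truth is internally consistent and causal variants sit within
  # 1 kb of planted-set gene bodies
  b2 <- sim_bundle(small_cfg())
  expect_length(b2$truth$causal_betas, length(b2$truth$causal_variant_ids))
  expect_true(all(b2$truth$causal_variant_ids %in%
                    b2$geno$variants$variant_id))
  asg <- assign_variants(
    b2$geno$variants[b2$geno$variants$variant_id %in%
                       b2$truth$causal_variant_ids, ], b2$annot)
  expect_true(all(asg$gene_id %in% b2$sets[[b2$cfg$planted_set_id]]))

  # determinism of the full bundle
  expect_identical(sim_bundle(small_cfg())$pheno, b2$pheno)
})

test_that("variance of line means matches lambda + 1/n_bar when beta = 0", {
  # with replicate_sd^2 = tau_inv, Var(line means)/tau_inv ~ lambda + 1/n
  ratios <- vapply(1:200, function(s) {
    cfg <- sim_config(n_lines = 40L, n_variants = 150L, n_blocks = 4L,
                      n_causal = 0L, lambda_true = 1, tau_inv = 400^2,
                      replicate_sd = 400, missing_rate = 0,
                      n_genes = 30L, chrom_length = 4e5, n_sets = 5L,
                      seed = s)
    b <- sim_bundle(cfg)
    s2 <- var(summarize_strains(b$pheno)$mean_px)
    s2 / cfg$tau_inv
  }, numeric(1))
  nbar <- 12.5
  expect_lt(abs(mean(ratios) - (1 + 1 / nbar)) / (1 + 1 / nbar), 0.15)
})

test_that("moment estimator on line means recovers the variance ratio", {
  # Haseman-Elston-style regression of the line-mean outer product on K:
  # with lambda = 1, tau_inv = replicate_sd^2 and 10-15 replicates the
  # fitted polygenic/residual ratio should be near 1 on average
  est <- vapply(1:60, function(s) {
    cfg <- sim_config(n_lines = 60L, n_variants = 300L, n_blocks = 6L,
                      n_causal = 0L, lambda_true = 1, tau_inv = 400^2,
                      replicate_sd = 400, missing_rate = 0,
                      n_genes = 30L, chrom_length = 4e5, n_sets = 5L,
                      seed = 5000 + s)
    b <- sim_bundle(cfg)
    sm <- summarize_strains(b$pheno)
    y <- sm$mean_px[match(b$geno$line_ids, sm$line_id)]
    K <- compute_grm(b$geno)$K
    K <- K / mean(diag(K))
    yc <- y - mean(y)
    P <- tcrossprod(yc)
    off <- !diag(TRUE, length(y))
    # slope of cross-products on kinship = polygenic variance
    vg <- sum(P[off] * K[off]) / sum(K[off]^2)
    vg / cfg$tau_inv
  }, numeric(1))
  expect_lt(abs(mean(est) - 1), 0.2)
})

test_that("knockdown experiment generator honours its contract", {
  flat <- simulate_rnai_experiment(17000, 0, c(a = 0, b = 0, c = 0), 10,
                                   seed = 4)
  expect_true(all(flat$eye_area_px == 17000))
  expect_equal(sort(unique(flat$line_id)), c("a", "b", "c", "control"))

  shifted <- simulate_rnai_experiment(17000, 100, c(kd = -1500), 15,
                                      seed = 4)
  m <- mean(shifted$eye_area_px[shifted$line_id == "kd"])
  se <- 100 / sqrt(15)
  expect_lt(abs(m - (17000 - 1500)), 5 * se)
  expect_identical(shifted,
                   simulate_rnai_experiment(17000, 100, c(kd = -1500), 15,
                                            seed = 4))
})
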
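# Synthetic DGRP-like panel generator: genotypes with block relatedness,
# gene models, gene sets, phenotypes with a planted causal pathway, and
# knockdown experiments. Everything is deterministic given the config seed.

# uniform draw from lo:hi that is safe when lo == hi
.sample_range <- function(lo, hi, n) lo + sample.int(hi - lo + 1L, n,
                                                     replace = TRUE) - 1L

#' Configuration for a synthetic inbred mapping panel
#'
#' Defaults emulate a DGRP-scale screen: ~200 fully homozygous lines,
#' common variants (MAF >= 0.05), block-structured relatedness, 10-15
#' phenotyped individuals per strain with within-strain noise of a few
#' hundred pixels, and causal variants concentrated in one planted gene
#' set so downstream enrichment can be verified against ground truth.
#'
#' @param n_lines number of inbred lines (>= 2).
#' @param n_variants number of biallelic variants.
#' @param n_blocks number of relatedness blocks; lines within a block share
#'   ancestral haplotypes, so their kinship exceeds the between-block level.
#' @param maf_range ancestral minor-allele-frequency range, within [0, 0.5].
#' @param missing_rate fraction of genotype calls set to missing.
#' @param lambda_true ratio of polygenic to residual variance (lambda >= 0)
#'   used when drawing the polygenic effect.
#' @param tau_inv residual variance of line means, in pixels^2 (> 0).
#' @param replicate_sd within-strain measurement SD in pixels.
#' @param n_replicates_range inclusive range of individuals measured per
#'   strain (default 10-15).
#' @param n_causal number of causal variants, all placed within 1 kb of
#'   genes belonging to the planted set.
#' @param causal_effect_size absolute causal effect in pixels per allele
#'   unit (genotypes are coded 0/2); signs are randomized.
#' @param planted_set_id identifier of the planted gene set.
#' @param baseline_px baseline eye area in pixels.
#' @param n_genes number of simulated gene models.
#' @param chrom_length chromosome length in bp.
#' @param n_sets number of gene sets (the first is the planted one).
#' @param set_size_range inclusive range of gene-set sizes.
#' @param mutation_rate per-line probability that a call is redrawn from
#'   the ancestral frequency instead of copied from the block haplotype;
#'   keeps marginal allele frequencies unbiased while diluting block
#'   sharing.
#' @param seed integer seed; together with the other fields it fully
#'   determines every simulated output.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_lines = 200L, n_variants = 5000L, n_blocks = 20L,
                       maf_range = c(0.05, 0.5), missing_rate = 0.02,
                       lambda_true = 1, tau_inv = 12800,
                       replicate_sd = 400,
                       n_replicates_range = c(10L, 15L),
                       n_causal = 20L, causal_effect_size = 300,
                       planted_set_id = "planted_pathway",
                       baseline_px = 14000,
                       n_genes = 300L, chrom_length = 3e6,
                       n_sets = 50L, set_size_range = c(4L, 50L),
                       mutation_rate = 0.25, seed = 1L) {
  cfg <- list(n_lines = as.integer(n_lines),
              n_variants = as.integer(n_variants),
              n_blocks = as.integer(n_blocks),
              maf_range = as.numeric(maf_range),
              missing_rate = missing_rate,
              lambda_true = lambda_true, tau_inv = tau_inv,
              replicate_sd = replicate_sd,
              n_replicates_range = as.integer(n_replicates_range),
              n_causal = as.integer(n_causal),
              causal_effect_size = causal_effect_size,
              planted_set_id = planted_set_id,
              baseline_px = baseline_px,
              n_genes = as.integer(n_genes),
              chrom_length = chrom_length,
              n_sets = as.integer(n_sets),
              set_size_range = as.integer(set_size_range),
              mutation_rate = mutation_rate,
              seed = as.integer(seed))
  if (cfg$n_lines < 2)
    stop("invalid config: n_lines must be >= 2", call. = FALSE)
  if (length(cfg$maf_range) != 2 || any(!is.finite(cfg$maf_range)) ||
      cfg$maf_range[1] > cfg$maf_range[2] ||
      cfg$maf_range[1] < 0 || cfg$maf_range[2] > 0.5)
    stop("invalid config: maf_range must be an ordered pair within [0, 0.5]",
         call. = FALSE)
  if (cfg$lambda_true < 0)
    stop("invalid config: lambda_true must be >= 0", call. = FALSE)
  if (cfg$tau_inv <= 0)
    stop("invalid config: tau_inv must be > 0", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("invalid config: missing_rate must be in [0, 1)", call. = FALSE)
  if (cfg$replicate_sd < 0)
    stop("invalid config: replicate_sd must be >= 0", call. = FALSE)
  if (cfg$n_replicates_range[1] < 1 ||
      cfg$n_replicates_range[1] > cfg$n_replicates_range[2])
    stop("invalid config: n_replicates_range must be an ordered pair >= 1",
         call. = FALSE)
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 1)
    stop("invalid config: mutation_rate must be in [0, 1]", call. = FALSE)
  if (cfg$n_blocks < 1 || cfg$n_blocks > cfg$n_lines)
    stop("invalid config: n_blocks must be in [1, n_lines]", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Simulate homozygous panel genotypes with block relatedness
#'
#' Lines are partitioned into `n_blocks` relatedness blocks. For each
#' variant an ancestral alternate-allele frequency is drawn uniformly from
#' `maf_range`; each block draws one ancestral allele at that frequency and
#' each line copies its block's allele, except that with probability
#' `mutation_rate` the call is redrawn independently from the ancestral
#' frequency. All calls are homozygous (0 or 2); a fraction `missing_rate`
#' is set to missing.
#'
#' @param cfg a [sim_config()].
#' @param chrom chromosome name used for all variants.
#' @return a [panel_genotypes()] object; the block assignment is attached
#'   as attribute `"blocks"`.
#' @export
simulate_genotypes <- function(cfg, chrom = "2R") {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_lines
    p <- cfg$n_variants
    if (cfg$chrom_length < p)
      stop("invalid config: chrom_length too small for n_variants",
           call. = FALSE)
    pos <- sort(sample.int(cfg$chrom_length, p))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, p, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    variants <- data.frame(
      variant_id = sprintf("%s_%d_SNP", chrom, pos),
      chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
      stringsAsFactors = FALSE)
    blocks <- sort(rep_len(seq_len(cfg$n_blocks), n))
    f <- runif(p, cfg$maf_range[1], cfg$maf_range[2])
    anc <- matrix(rbinom(cfg$n_blocks * p, 1L, rep(f, each = cfg$n_blocks)),
                  cfg$n_blocks, p)
    allele <- anc[blocks, , drop = FALSE]
    if (cfg$mutation_rate > 0) {
      mut <- matrix(runif(n * p) < cfg$mutation_rate, n, p)
      redraw <- matrix(rbinom(n * p, 1L, rep(f, each = n)), n, p)
      allele[mut] <- redraw[mut]
    }
    geno <- 2 * allele
    if (cfg$missing_rate > 0)
      geno[matrix(runif(n * p) < cfg$missing_rate, n, p)] <- NA
    out <- panel_genotypes(sprintf("line%03d", seq_len(n)), variants, geno)
    attr(out, "blocks") <- blocks
    out
  })
}

#' Simulate gene models on a single chromosome
#'
#' Genes are placed left to right with random lengths and gaps; each gene
#' has 1-4 exons and, usually, terminal UTRs. Two deliberate edge cases are
#' always present when the gene count allows: the first two genes are less
#' than 2 kb apart, and one intergenic gap of at least 4 kb guarantees a
#' region more than 1 kb away from any gene body.
#'
#' @param n_genes number of genes (>= 1).
#' @param chrom_length chromosome length in bp.
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return a [gene_annotation()] object.
#' @export
simulate_annotation <- function(n_genes, chrom_length, seed = 1L,
                                chrom = "2R") {
  if (n_genes < 1) stop("invalid config: n_genes must be >= 1",
                        call. = FALSE)
  withr::with_seed(as.integer(seed), {
    lens <- sample(1000:6000, n_genes, replace = TRUE)
    gaps <- sample(1500:8000, n_genes, replace = TRUE)
    gaps[1] <- sample(500:3000, 1L)              # offset of first gene
    if (n_genes >= 2) gaps[2] <- sample(200:1800, 1L)  # close gene pair
    if (n_genes >= 3) gaps[3] <- sample(4000:9000, 1L) # wide desert
    starts <- cumsum(gaps) + cumsum(c(0, lens[-n_genes]))
    ends <- starts + lens - 1L
    if (ends[n_genes] > chrom_length)
      stop("invalid config: chrom_length too small to place n_genes",
           call. = FALSE)
    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(n_genes)),
      chrom = chrom, start = starts, end = ends,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      stringsAsFactors = FALSE)
    exons <- list(); utrs <- list()
    for (i in seq_len(n_genes)) {
      L <- lens[i]
      n_ex <- sample(1:4, 1L)
      n_seg <- 2L * n_ex - 1L          # exon, intron, exon, ...
      if (L < 40L * n_seg) { n_ex <- 1L; n_seg <- 1L }
      w <- runif(n_seg)
      widths <- 40L + floor((L - 40L * n_seg) * w / sum(w))
      widths[n_seg] <- L - sum(widths[-n_seg])
      bounds <- starts[i] + c(0L, cumsum(widths))
      ex_idx <- seq(1L, n_seg, by = 2L)
      ex <- data.frame(gene_id = genes$gene_id[i],
                       start = bounds[ex_idx],
                       end = bounds[ex_idx + 1L] - 1L)
      exons[[i]] <- ex
      if (runif(1) < 0.7) {
        first <- ex[1, ]; last <- ex[nrow(ex), ]
        u5 <- c(first$start,
                min(first$end, first$start + sample(30:200, 1L)))
        u3 <- c(max(last$start, last$end - sample(30:200, 1L)), last$end)
        plus <- genes$strand[i] == "+"
        utrs[[length(utrs) + 1L]] <- data.frame(
          gene_id = genes$gene_id[i],
          start = c(u5[1], u3[1]), end = c(u5[2], u3[2]),
          side = if (plus) c("five_prime", "three_prime")
                 else c("three_prime", "five_prime"))
      }
    }
    utrs <- if (length(utrs)) do.call(rbind, utrs) else
      data.frame(gene_id = character(), start = integer(),
                 end = integer(), side = character())
    gene_annotation(genes, do.call(rbind, exons), utrs)
  })
}

#' Simulate gene sets
#'
#' Draws `n_sets` gene sets by sampling genes without replacement within
#' each set; the first set carries `planted_set_id` and is the one the
#' phenotype simulator loads with causal variants.
#'
#' @param genes character vector of gene ids to sample from.
#' @param n_sets number of sets.
#' @param size_range inclusive range of set sizes.
#' @param planted_set_id id given to the first (planted) set.
#' @param seed integer seed.
#' @return a named list of character vectors (class `gene_sets`), with a
#'   `descriptions` attribute.
#' @export
simulate_gene_sets <- function(genes, n_sets, size_range = c(4L, 50L),
                               planted_set_id = "planted_pathway",
                               seed = 1L) {
  if (size_range[1] > length(genes))
    stop("invalid config: requested set size exceeds number of genes",
         call. = FALSE)
  withr::with_seed(as.integer(seed), {
    hi <- min(size_range[2], length(genes))
    sizes <- .sample_range(size_range[1], hi, n_sets)
    sets <- lapply(sizes, function(k)
      sort(genes[sample.int(length(genes), k)]))
    ids <- c(planted_set_id,
             if (n_sets > 1) sprintf("set%03d", seq_len(n_sets - 1L)))
    names(sets) <- ids
    structure(sets,
              descriptions = setNames(
                c("planted causal pathway",
                  rep("random gene set", n_sets - 1L)), ids),
              class = "gene_sets")
  })
}

#' Simulate per-individual phenotypes with a planted causal pathway
#'
#' Inverts the association model: each line receives a genetic value
#' `g = sum(x * beta) + u` where the causal variants lie within 1 kb of
#' genes in the planted set and `u ~ MVN(0, lambda_true * tau_inv * Ks)`.
#' `Ks` is the panel's centered relatedness matrix rescaled to unit mean
#' diagonal, so `lambda_true` is the per-line polygenic/residual variance
#' ratio. Each line is then measured `n_replicates_range` times with
#' N(0, replicate_sd^2) noise around `baseline_px + g`.
#'
#' @param geno a [panel_genotypes()] object.
#' @param annot a [gene_annotation()] object.
#' @param sets a `gene_sets` collection containing `cfg$planted_set_id`.
#' @param cfg a [sim_config()].
#' @return list with elements `phenotypes` (per-individual table with
#'   columns line_id, sex, replicate, eye_area_px) and `truth` (list with
#'   causal_variant_ids, causal_betas, planted_set_id,
#'   per_line_genetic_values).
#' @export
simulate_phenotypes <- function(geno, annot, sets, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$lambda_true < 0 || cfg$tau_inv <= 0)
    stop("invalid config: lambda_true < 0 or tau_inv <= 0", call. = FALSE)
  planted <- sets[[cfg$planted_set_id]]
  if (is.null(planted))
    stop("planted set '", cfg$planted_set_id, "' not found", call. = FALSE)
  withr::with_seed(cfg$seed + 1000003L, {
    n <- n_lines(geno)
    v <- geno$variants
    causal_ids <- character(0)
    betas <- numeric(0)
    g_fixed <- rep(0, n)
    if (cfg$n_causal > 0) {
      pg <- annot$genes[annot$genes$gene_id %in% planted, , drop = FALSE]
      in_window <- rep(FALSE, nrow(v))
      for (i in seq_len(nrow(pg)))
        in_window <- in_window |
          (v$chrom == pg$chrom[i] & v$pos >= pg$start[i] - 1000 &
             v$pos <= pg$end[i] + 1000)
      cand <- which(in_window)
      if (length(cand) < cfg$n_causal)
        stop("only ", length(cand), " variants available near the planted ",
             "set; n_causal = ", cfg$n_causal, call. = FALSE)
      causal <- sort(cand[sample.int(length(cand), cfg$n_causal)])
      causal_ids <- v$variant_id[causal]
      betas <- cfg$causal_effect_size *
        sample(c(-1, 1), cfg$n_causal, replace = TRUE)
      X <- geno$geno[, causal, drop = FALSE]
      for (j in seq_len(ncol(X))) {
        xj <- X[, j]
        xj[is.na(xj)] <- mean(xj, na.rm = TRUE)
        X[, j] <- xj
      }
      g_fixed <- drop(X %*% betas)
    }
    u <- rep(0, n)
    sigma_u <- cfg$lambda_true * cfg$tau_inv
    if (sigma_u > 0) {
      K <- compute_grm(geno)$K
      Ks <- K / mean(diag(K))
      R <- chol(Ks + diag(1e-8, n))
      u <- sqrt(sigma_u) * drop(crossprod(R, rnorm(n)))
    }
    g <- g_fixed + u
    reps <- .sample_range(cfg$n_replicates_range[1],
                          cfg$n_replicates_range[2], n)
    pheno <- data.frame(
      line_id = rep(geno$line_ids, reps),
      sex = "F",
      replicate = unlist(lapply(reps, seq_len)),
      eye_area_px = rep(cfg$baseline_px + g, reps) +
        rnorm(sum(reps), 0, cfg$replicate_sd),
      stringsAsFactors = FALSE)
    truth <- list(causal_variant_ids = causal_ids,
                  causal_betas = betas,
                  planted_set_id = cfg$planted_set_id,
                  per_line_genetic_values = setNames(g, geno$line_ids))
    list(phenotypes = pheno, truth = truth)
  })
}

#' Simulate a knockdown validation experiment
#'
#' One control group plus one knockdown group per entry of `effects`,
#' each with `n_per_group` individuals drawn from
#' N(control_mean + effect, control_sd^2).
#'
#' @param control_mean control group mean eye area (pixels).
#' @param control_sd within-group SD (pixels, >= 0).
#' @param effects numeric vector of mean shifts in pixels; names become
#'   group ids (default `kd1`, `kd2`, ...).
#' @param n_per_group individuals per group (>= 2).
#' @param seed integer seed.
#' @param control_id id for the control group.
#' @return a per-individual phenotype table (line_id, sex, replicate,
#'   eye_area_px).
#' @export
simulate_rnai_experiment <- function(control_mean, control_sd, effects,
                                     n_per_group, seed = 1L,
                                     control_id = "control") {
  if (control_sd < 0)
    stop("invalid config: control_sd must be >= 0", call. = FALSE)
  if (n_per_group < 2)
    stop("invalid config: n_per_group must be >= 2", call. = FALSE)
  ids <- names(effects)
  if (is.null(ids)) ids <- sprintf("kd%d", seq_along(effects))
  withr::with_seed(as.integer(seed), {
    means <- c(setNames(control_mean, control_id), control_mean + setNames(effects, ids))
    data.frame(
      line_id = rep(names(means), each = n_per_group),
      sex = "F",
      replicate = rep(seq_len(n_per_group), length(means)),
      eye_area_px = rnorm(n_per_group * length(means),
                          rep(unname(means), each = n_per_group),
                          control_sd),
      stringsAsFactors = FALSE)
  })
}
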
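# One-call orchestration of the screen: simulate (or load) a panel,
# filter variants, build the relatedness matrix, scan, assign variants to
# genes, run the gene-set enrichment, and leave auditable plain-text
# outputs plus a manifest behind.

#' Read a flat key-value screen configuration
#'
#' A YAML file of scalar keys. Either `geno`, `pheno`, `gff`, `gmt` point
#' at input files, or `simulate: true` plus any [sim_config()] fields
#' requests a synthetic panel. Threshold keys (`maf_min`, `max_missing`,
#' `p_cutoff`, `n_perm`, `min_genes`, `window`) override the stage
#' defaults; `seed` drives every random draw.
#'
#' @param path YAML config file.
#' @return named list.
#' @export
read_screen_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a key-value mapping",
                          call. = FALSE)
  cfg
}

#' Run the full modifier screen
#'
#' Stages: input (simulation or files) -> variant filter -> relatedness
#' matrix -> mixed-model scan -> variant-to-gene assignment -> gene-set
#' enrichment -> QQ diagnostics. Writes `assoc.tsv`, `assignments.tsv`,
#' `gsea.tsv`, `qq.tsv`, `candidates.tsv`, `phenotypes.csv`,
#' `manifest.json` (plus `truth.json` for simulated inputs) into
#' `out_dir`. Every threshold actually applied is recorded in the
#' manifest, and file digests make reruns comparable.
#'
#' @param config a list (or path to a YAML file, see
#'   [read_screen_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results
#'   (`assoc`, `assignments`, `gsea`, `filtered_sets`, `candidates`,
#'   `qq`, `manifest`, and `truth` when simulated).
#' @export
run_screen <- function(config, out_dir) {
  if (is.character(config)) config <- read_screen_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  get <- function(key, default) if (!is.null(config[[key]]))
    config[[key]] else default
  seed <- as.integer(get("seed", 1L))
  simulate <- isTRUE(get("simulate", is.null(config$geno)))

  if (simulate) {
    sim_keys <- setdiff(intersect(names(config),
                                  names(formals(sim_config))), "seed")
    cfg <- do.call(sim_config, c(config[sim_keys], list(seed = seed)))
    geno <- simulate_genotypes(cfg)
    annot <- simulate_annotation(cfg$n_genes, cfg$chrom_length,
                                 seed = seed)
    sets <- simulate_gene_sets(annot$genes$gene_id, cfg$n_sets,
                               cfg$set_size_range,
                               planted_set_id = cfg$planted_set_id,
                               seed = seed)
    sim <- simulate_phenotypes(geno, annot, sets, cfg)
    pheno <- sim$phenotypes
    truth <- sim$truth
  } else {
    for (key in c("geno", "pheno", "gff", "gmt"))
      if (is.null(config[[key]]) || !file.exists(config[[key]]))
        stop("config error: missing or unreadable input '", key, "'",
             call. = FALSE)
    geno <- read_genotypes(config$geno)
    pheno <- read_phenotypes(config$pheno)
    annot <- read_annotation(config$gff)
    sets <- read_gene_sets(config$gmt)
    truth <- NULL
  }

  fail <- function(stage, e)
    stop("stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  summaries <- tryCatch(summarize_strains(pheno, sex_filter = "F"),
                        error = function(e) fail("phenotype_summary", e))
  maf_min <- get("maf_min", 0.05)
  max_missing <- get("max_missing", 0.20)
  filtered <- tryCatch(filter_variants(geno, maf_min, max_missing),
                       error = function(e) fail("variant_filter", e))
  K <- tryCatch(compute_grm(filtered),
                error = function(e) fail("grm", e))
  assoc <- tryCatch(
    run_gwas(summaries, filtered, K,
             min_lines = get("min_lines", 30)),
    error = function(e) fail("gwas", e))
  window <- get("window", 1000)
  assignments <- tryCatch(assign_variants(assoc, annot, window),
                          error = function(e) fail("assignment", e))
  p_cutoff <- get("p_cutoff", 1e-4)
  candidates <- tryCatch(candidate_genes(assignments, assoc, p_cutoff),
                         error = function(e) fail("candidates", e))
  ranked <- tryCatch(rank_genes(assignments, assoc),
                     error = function(e) fail("gene_ranking", e))
  n_perm <- get("n_perm", 1000)
  gsea <- tryCatch(
    permutation_significance(ranked, sets, n_perm = n_perm,
                             seed = seed),
    error = function(e) fail("gsea", e))
  filtered_sets <- filter_gene_set_results(
    gsea, min_genes = get("min_genes", 4),
    p_adj_max = get("p_adj_max", 0.05))
  qq <- tryCatch(qq_diagnostics(assoc),
                 error = function(e) fail("qq", e))

  fp <- function(name) file.path(out_dir, name)
  write_assoc_results(assoc, fp("assoc.tsv"))
  utils::write.table(assignments, fp("assignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(gsea), fp("gsea.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(expected = qq$expected, observed = qq$observed),
    fp("qq.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(candidates$genes, fp("candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_phenotypes(pheno, fp("phenotypes.csv"))
  if (!is.null(truth))
    jsonlite::write_json(
      list(causal_variant_ids = truth$causal_variant_ids,
           causal_betas = truth$causal_betas,
           planted_set_id = truth$planted_set_id,
           per_line_genetic_values =
             as.list(truth$per_line_genetic_values)),
      fp("truth.json"), auto_unbox = TRUE, digits = NA)

  stage_files <- c("assoc.tsv", "assignments.tsv", "gsea.tsv", "qq.tsv",
                   "candidates.tsv", "phenotypes.csv")
  manifest <- list(
    tool = "modscreen",
    version = as.character(utils::packageVersion("modscreen")),
    seed = seed,
    thresholds = list(maf_min = maf_min, max_missing = max_missing,
                      p_cutoff = p_cutoff, window = window,
                      n_perm = n_perm,
                      min_genes = get("min_genes", 4),
                      p_adj_max = get("p_adj_max", 0.05)),
    counts = list(
      n_lines = length(geno$line_ids),
      n_variants_input = n_variants(geno),
      n_variants_filtered = n_variants(filtered),
      n_variants_tested = nrow(assoc),
      n_candidate_genes = nrow(candidates$genes),
      n_genes_ranked = nrow(ranked),
      n_sets_tested = nrow(gsea),
      n_sets_passing = nrow(filtered_sets)),
    lambda_gc = qq$lambda_gc,
    digests = as.list(tools::md5sum(file.path(out_dir, stage_files))))
  names(manifest$digests) <- stage_files
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(assoc = assoc, assignments = assignments,
                 candidates = candidates, ranked = ranked, gsea = gsea,
                 filtered_sets = filtered_sets, qq = qq,
                 summaries = summaries, manifest = manifest,
                 truth = truth))
}

#' Summarize a finished screen run
#'
#' Reads the stage files left by [run_screen()] and prints a
#' human-readable summary: candidate genes below the p cutoff (best p
#' first), gene sets surviving the reporting filter, and the
#' genomic-inflation factor. Counts are recomputed from the files, so the
#' report is an independent audit of the manifest.
#'
#' @param out_dir directory written by [run_screen()].
#' @return invisibly, a list with `candidates`, `gene_sets`, `lambda_gc`
#'   and `counts`.
#' @export
report_screen <- function(out_dir) {
  need <- c("assoc.tsv", "assignments.tsv", "gsea.tsv", "qq.tsv",
            "candidates.tsv", "manifest.json")
  for (f in need)
    if (!file.exists(file.path(out_dir, f)))
      stop("missing stage file: ", f, call. = FALSE)
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  assoc <- read_assoc_results(file.path(out_dir, "assoc.tsv"))
  candidates <- utils::read.delim(file.path(out_dir, "candidates.tsv"),
                                  stringsAsFactors = FALSE)
  gsea <- utils::read.delim(file.path(out_dir, "gsea.tsv"),
                            stringsAsFactors = FALSE)
  passing <- filter_gene_set_results(
    gsea, min_genes = manifest$thresholds$min_genes,
    p_adj_max = manifest$thresholds$p_adj_max)
  lambda_gc <- qq_diagnostics(assoc)$lambda_gc
  counts <- list(n_variants_tested = nrow(assoc),
                 n_candidate_genes = nrow(candidates),
                 n_sets_tested = nrow(gsea),
                 n_sets_passing = nrow(passing))
  cat(sprintf("modscreen run: %d variants tested, lambda_GC = %.3f\n",
              counts$n_variants_tested, lambda_gc))
  if (nrow(candidates)) {
    cat(sprintf("%d candidate gene(s) at p < %g:\n",
                nrow(candidates), manifest$thresholds$p_cutoff))
    top <- candidates[order(candidates$min_p, candidates$gene_id), ]
    for (i in seq_len(min(10, nrow(top))))
      cat(sprintf("  %s  (%d variant(s), min p = %.3g)\n",
                  top$gene_id[i], top$n_variants[i], top$min_p[i]))
  } else {
    cat("zero candidate genes at the p cutoff\n")
  }
  if (nrow(passing)) {
    cat(sprintf("%d enriched gene set(s) pass the reporting filter:\n",
                nrow(passing)))
    for (i in seq_len(min(10, nrow(passing))))
      cat(sprintf("  %s  (ES = %.3f, %d genes, adj p = %.3g)\n",
                  passing$set_id[i], passing$es[i],
                  passing$n_genes_present[i], passing$p_adjusted[i]))
  } else {
    cat("no gene set passes the reporting filter\n")
  }
  invisible(list(candidates = candidates, gene_sets = passing,
                 lambda_gc = lambda_gc, counts = counts))
}
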
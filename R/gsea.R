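# Variant-level gene set enrichment: genes are scored by their best
# variant p-value, ranked, and each set is tested with the weighted
# Kolmogorov-Smirnov running-sum statistic against a gene-label
# permutation null.

#' Rank genes by their best associated variant
#'
#' Each gene's score is `-log10` of the minimum Wald p-value across its
#' assigned variants (intergenic variants are excluded). Genes are sorted
#' by descending score; ties break lexicographically by gene id so the
#' ranking is reproducible.
#'
#' @param assignments output of [assign_variants()].
#' @param assoc association results with `variant_id` and `p_wald`.
#' @return data frame with columns `gene_id`, `score`, in ranked order.
#' @export
rank_genes <- function(assignments, assoc) {
  m <- merge(assignments, assoc[, c("variant_id", "p_wald")],
             by = "variant_id")
  m <- m[m$gene_id != "INTERGENIC", , drop = FALSE]
  if (!nrow(m))
    stop("no gene-assigned variants to rank", call. = FALSE)
  minp <- tapply(m$p_wald, m$gene_id, min)
  out <- data.frame(gene_id = names(minp),
                    score = -log10(as.numeric(minp)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Signed maximum deviation of the running sum for hits at `hit_idx`
# (positions in the ranked list). s_pow is |score|^weight_p.
.es_core <- function(s_pow, hit_idx, N) {
  Nh <- length(hit_idx)
  step <- rep.int(-1 / (N - Nh), N)
  wsum <- sum(s_pow[hit_idx])
  step[hit_idx] <- if (wsum > 0) s_pow[hit_idx] / wsum else 1 / Nh
  running <- cumsum(step)
  i <- which.max(abs(running))
  list(es = running[i], running = running, arg = i)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: set members ("hits") add `|score|^weight_p`
#' normalized by the total over hits; non-members subtract `1/(N - Nh)`.
#' The enrichment score is the running sum's maximum deviation from zero,
#' signed. `weight_p = 0` reduces to the classical two-sample KS statistic
#' on ranks; `weight_p = 1` (default) is the standard score-weighted form.
#'
#' @param ranked ranked gene list from [rank_genes()].
#' @param set_genes character vector of member gene ids.
#' @param weight_p score weight exponent.
#' @return list with `es`, `running` (the N-step running sum) and
#'   `leading_edge` (members at or before the extremum for positive ES,
#'   at or after it for negative ES).
#' @export
enrichment_score <- function(ranked, set_genes, weight_p = 1) {
  N <- nrow(ranked)
  hit_idx <- which(ranked$gene_id %in% set_genes)
  if (!length(hit_idx))
    stop("gene set has no members in the ranked list", call. = FALSE)
  if (length(hit_idx) == N)
    stop("degenerate set: covers the entire ranked list (no misses)",
         call. = FALSE)
  s_pow <- abs(ranked$score)^weight_p
  r <- .es_core(s_pow, hit_idx, N)
  le_idx <- if (r$es >= 0) hit_idx[hit_idx <= r$arg]
            else hit_idx[hit_idx >= r$arg]
  list(es = r$es, running = r$running,
       leading_edge = ranked$gene_id[le_idx])
}

#' Permutation significance for gene sets
#'
#' For each set present in the ranked list, the null is built by
#' resampling the same number of gene labels without replacement
#' `n_perm` times. The nominal p uses the add-one convention on the
#' same-sign tail: `(1 + #[ES_perm >= ES_obs]) / (1 + n_perm)` for
#' positive observed ES, mirrored for negative. NES divides the observed
#' ES by the mean same-sign permuted ES, and Benjamini-Hochberg corrects
#' across all tested sets.
#'
#' @param ranked ranked gene list from [rank_genes()].
#' @param sets a `gene_sets` collection (named list of gene id vectors).
#' @param n_perm number of permutations (>= 100).
#' @param weight_p score weight exponent.
#' @param seed integer seed for the permutation draws.
#' @return data frame of class `gene_set_results` with columns `set_id`,
#'   `n_genes_present`, `es`, `nes`, `p_nominal`, `p_adjusted`,
#'   `leading_edge` (semicolon-joined).
#' @export
permutation_significance <- function(ranked, sets, n_perm = 1000,
                                     weight_p = 1, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  N <- nrow(ranked)
  s_pow <- abs(ranked$score)^weight_p
  present <- lapply(sets, function(g) which(ranked$gene_id %in% g))
  usable <- vapply(present, function(i)
    length(i) >= 1L && length(i) < N, logical(1))
  if (!any(usable)) {
    warning("no gene set has members in the ranked list", call. = FALSE)
    return(structure(data.frame(set_id = character(),
                                n_genes_present = integer(), es = numeric(),
                                nes = numeric(), p_nominal = numeric(),
                                p_adjusted = numeric(),
                                leading_edge = character(),
                                stringsAsFactors = FALSE),
                     class = c("gene_set_results", "data.frame")))
  }
  if (any(!usable))
    warning(sum(!usable), " set(s) skipped (no members in ranked list, ",
            "or no misses)", call. = FALSE)
  sets_use <- names(sets)[usable]
  res <- withr::with_seed(as.integer(seed), {
    lapply(sets_use, function(id) {
      hit_idx <- present[[id]]
      Nh <- length(hit_idx)
      obs <- .es_core(s_pow, hit_idx, N)
      perm <- vapply(seq_len(n_perm), function(b)
        .es_core(s_pow, sample.int(N, Nh), N)$es, numeric(1))
      p_nom <- if (obs$es >= 0)
        (1 + sum(perm >= obs$es)) / (1 + n_perm)
      else (1 + sum(perm <= obs$es)) / (1 + n_perm)
      same_sign <- if (obs$es >= 0) perm[perm > 0] else perm[perm < 0]
      nes <- if (length(same_sign)) obs$es / mean(same_sign) else NA_real_
      le_idx <- if (obs$es >= 0) hit_idx[hit_idx <= obs$arg]
                else hit_idx[hit_idx >= obs$arg]
      data.frame(set_id = id, n_genes_present = Nh, es = obs$es,
                 nes = nes, p_nominal = p_nom,
                 leading_edge = paste(ranked$gene_id[le_idx],
                                      collapse = ";"),
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- p.adjust(out$p_nominal, method = "BH")
  out <- out[, c("set_id", "n_genes_present", "es", "nes", "p_nominal",
                 "p_adjusted", "leading_edge")]
  rownames(out) <- NULL
  class(out) <- c("gene_set_results", "data.frame")
  out
}

#' Reporting filter for gene-set results
#'
#' Keeps sets that are enriched at the top of the list (`es > es_min`,
#' sets with ES <= 0 are unenriched), supported by multiple genes
#' (`n_genes_present >= min_genes`, i.e. strictly more than
#' `min_genes - 1`), and significant after correction
#' (`p_adjusted < p_adj_max`, strict).
#'
#' @param results a `gene_set_results` data frame.
#' @param es_min exclusive lower bound on ES (default 0).
#' @param min_genes minimum member count present (default 4, i.e.
#'   "more than 3 genes").
#' @param p_adj_max strict upper bound on the corrected p (default 0.05).
#' @return the filtered data frame, ordered by `p_nominal` then set id.
#' @export
filter_gene_set_results <- function(results, es_min = 0, min_genes = 4,
                                    p_adj_max = 0.05) {
  keep <- results$es > es_min &
    results$n_genes_present >= min_genes &
    results$p_adjusted < p_adj_max
  out <- results[keep, , drop = FALSE]
  out <- out[order(out$p_nominal, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
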
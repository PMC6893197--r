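# Variant-to-gene assignment: a variant belongs to a gene if it lies
# within the gene body or within 1 kb of it (inclusive). When several
# genes are in range the feature category decides:
# exon > UTR > intron > upstream/downstream (one flank tier), with ties
# broken by distance and then lexicographic gene id, so assignment is
# independent of gene input order.

.category_priority <- c(exon = 4, UTR = 3, intron = 2,
                        upstream = 1, downstream = 1)

#' Classify a position relative to one gene model
#'
#' Inside the gene span the category is `UTR` if the position falls in an
#' annotated UTR interval (UTRs are exonic subregions and outrank plain
#' exon), `exon` if in an exon, otherwise `intron`. Within `window` bp of
#' the span the category is `upstream` or `downstream` by strand (on the
#' minus strand, upstream is the high-coordinate side). Beyond the window
#' (or on another chromosome) the result is `"none"`.
#'
#' @param chrom,pos variant coordinate (1-based).
#' @param gene_id gene to classify against.
#' @param annot a [gene_annotation()] object.
#' @param window flank size in bp, inclusive at exactly `window`.
#' @return one of `"exon"`, `"UTR"`, `"intron"`, `"upstream"`,
#'   `"downstream"`, `"none"`.
#' @export
classify_variant <- function(chrom, pos, gene_id, annot, window = 1000) {
  g <- annot$genes[annot$genes$gene_id == gene_id, , drop = FALSE]
  if (!nrow(g)) stop("unknown gene_id: ", gene_id, call. = FALSE)
  if (g$chrom != chrom) return("none")
  if (pos >= g$start && pos <= g$end) {
    ut <- annot$utrs[annot$utrs$gene_id == gene_id, , drop = FALSE]
    if (nrow(ut) && any(pos >= ut$start & pos <= ut$end)) return("UTR")
    ex <- annot$exons[annot$exons$gene_id == gene_id, , drop = FALSE]
    if (any(pos >= ex$start & pos <= ex$end)) return("exon")
    return("intron")
  }
  if (pos >= g$start - window && pos < g$start)
    return(if (g$strand == "+") "upstream" else "downstream")
  if (pos > g$end && pos <= g$end + window)
    return(if (g$strand == "+") "downstream" else "upstream")
  "none"
}

#' Assign one variant to its best gene
#'
#' Among genes whose body lies within `window` bp of the variant, picks
#' the gene whose category has the highest priority
#' (exon > UTR > intron > flank); equal-priority ties go to the nearer
#' gene body, then to the lexicographically smaller gene id. With no gene
#' in range the variant is `INTERGENIC`.
#'
#' @param chrom,pos variant coordinate.
#' @param variant_id variant identifier carried into the result.
#' @param annot a [gene_annotation()] object.
#' @param window flank size in bp.
#' @return list with `variant_id`, `gene_id` (or `"INTERGENIC"`),
#'   `category`, `distance_bp` (0 inside a gene body).
#' @export
assign_variant <- function(chrom, pos, variant_id, annot, window = 1000) {
  g <- annot$genes
  cand <- which(g$chrom == chrom & pos >= g$start - window &
                  pos <= g$end + window)
  if (!length(cand))
    return(list(variant_id = variant_id, gene_id = "INTERGENIC",
                category = "intergenic", distance_bp = NA_real_))
  cats <- vapply(g$gene_id[cand], function(gid)
    classify_variant(chrom, pos, gid, annot, window), "")
  dist <- pmax(0, pmax(g$start[cand] - pos, pos - g$end[cand]))
  prio <- .category_priority[cats]
  ord <- order(-prio, dist, g$gene_id[cand])[1]
  list(variant_id = variant_id, gene_id = g$gene_id[cand][ord],
       category = unname(cats[ord]), distance_bp = unname(dist[ord]))
}

#' Assign every variant of a panel (or table) to genes
#'
#' @param variants a [panel_genotypes()] object or a data frame with
#'   columns `variant_id`, `chrom`, `pos`.
#' @param annot a [gene_annotation()] object.
#' @param window flank size in bp.
#' @return data frame with columns `variant_id`, `gene_id`, `category`,
#'   `distance_bp`; exactly one row per input variant.
#' @export
assign_variants <- function(variants, annot, window = 1000) {
  if (inherits(variants, "panel_genotypes")) variants <- variants$variants
  rows <- lapply(seq_len(nrow(variants)), function(i)
    assign_variant(variants$chrom[i], variants$pos[i],
                   variants$variant_id[i], annot, window))
  out <- data.frame(
    variant_id = vapply(rows, `[[`, "", "variant_id"),
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    category = vapply(rows, `[[`, "", "category"),
    distance_bp = vapply(rows, `[[`, numeric(1), "distance_bp"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Candidate genes at a p-value cutoff
#'
#' Variants with `p_wald` strictly below `p_cutoff` are grouped by their
#' assigned gene; intergenic hits are reported separately. Genes are
#' ordered by their best (minimum) supporting p-value.
#'
#' @param assignments output of [assign_variants()].
#' @param assoc association results with `variant_id` and `p_wald`.
#' @param p_cutoff strict upper bound on the Wald p-value (default 1e-4,
#'   the conventional suggestive threshold for panel-scale scans).
#' @return list with `genes` (data frame: gene_id, n_variants, min_p,
#'   variant_ids semicolon-joined) and `intergenic` (data frame:
#'   variant_id, p_wald).
#' @export
candidate_genes <- function(assignments, assoc, p_cutoff = 1e-4) {
  if (!is.numeric(p_cutoff) || p_cutoff <= 0 || p_cutoff >= 1)
    stop("p_cutoff must lie in (0, 1)", call. = FALSE)
  m <- merge(assignments, assoc[, c("variant_id", "p_wald")],
             by = "variant_id")
  if (nrow(m) < nrow(assoc))
    stop("assignments do not cover all association variants",
         call. = FALSE)
  hit <- m[m$p_wald < p_cutoff, , drop = FALSE]
  inter <- hit[hit$gene_id == "INTERGENIC",
               c("variant_id", "p_wald"), drop = FALSE]
  genic <- hit[hit$gene_id != "INTERGENIC", , drop = FALSE]
  if (nrow(genic)) {
    sp <- split(genic, genic$gene_id)
    genes <- data.frame(
      gene_id = names(sp),
      n_variants = vapply(sp, nrow, integer(1)),
      min_p = vapply(sp, function(d) min(d$p_wald), numeric(1)),
      variant_ids = vapply(sp, function(d)
        paste(d$variant_id[order(d$p_wald, d$variant_id)],
              collapse = ";"), ""),
      stringsAsFactors = FALSE)
    genes <- genes[order(genes$min_p, genes$gene_id), , drop = FALSE]
  } else {
    genes <- data.frame(gene_id = character(), n_variants = integer(),
                        min_p = numeric(), variant_ids = character(),
                        stringsAsFactors = FALSE)
  }
  rownames(genes) <- rownames(inter) <- NULL
  list(genes = genes, intergenic = inter)
}
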
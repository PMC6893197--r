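# Core data containers shared by every stage of the screen.

#' Construct a panel genotype object
#'
#' A `panel_genotypes` object holds the line-by-variant genotype matrix of a
#' homozygous inbred panel together with variant metadata. Calls are coded
#' 0 (homozygous reference), 2 (homozygous alternate) or `NA` (missing);
#' heterozygotes never appear because panel strains are isogenic.
#'
#' @param line_ids character vector of unique strain identifiers.
#' @param variants data frame with columns `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt` (multi-allelic records keep a comma-joined `alt`).
#' @param geno numeric matrix, `length(line_ids)` rows by `nrow(variants)`
#'   columns, values in \{0, 2, NA\}.
#' @return an object of class `panel_genotypes` with elements `line_ids`,
#'   `variants` and `geno`.
#' @export
panel_genotypes <- function(line_ids, variants, geno) {
  line_ids <- as.character(line_ids)
  if (anyDuplicated(line_ids))
    stop("line_ids must be unique", call. = FALSE)
  need <- c("variant_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variants is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant_id in variants table", call. = FALSE)
  if (any(variants$pos < 1, na.rm = TRUE))
    stop("variant pos must be >= 1", call. = FALSE)
  geno <- as.matrix(geno)
  if (nrow(geno) != length(line_ids) || ncol(geno) != nrow(variants))
    stop("geno must be length(line_ids) x nrow(variants)", call. = FALSE)
  bad <- !(geno %in% c(0, 2)) & !is.na(geno)
  if (any(bad))
    stop("genotype calls must be 0, 2 or NA", call. = FALSE)
  dimnames(geno) <- list(line_ids, variants$variant_id)
  rownames(variants) <- NULL
  structure(list(line_ids = line_ids, variants = variants, geno = geno),
            class = "panel_genotypes")
}

#' @export
print.panel_genotypes <- function(x, ...) {
  cat(sprintf("panel_genotypes: %d lines x %d variants (%.1f%% missing)\n",
              length(x$line_ids), nrow(x$variants),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Number of lines / variants in a panel
#' @param geno a `panel_genotypes` object.
#' @return integer count.
#' @export
n_lines <- function(geno) length(geno$line_ids)

#' @rdname n_lines
#' @export
n_variants <- function(geno) nrow(geno$variants)

#' Subset a panel to selected variants or lines
#'
#' @param geno a `panel_genotypes` object.
#' @param variant_idx index (logical, integer or variant id) into the
#'   variant table; default keeps all.
#' @param line_idx index (logical, integer or line id) into the lines;
#'   default keeps all.
#' @return a `panel_genotypes` object.
#' @export
subset_panel <- function(geno, variant_idx = NULL, line_idx = NULL) {
  v <- geno$variants
  g <- geno$geno
  lines <- geno$line_ids
  if (!is.null(variant_idx)) {
    if (is.character(variant_idx))
      variant_idx <- match(variant_idx, v$variant_id)
    v <- v[variant_idx, , drop = FALSE]
    g <- g[, variant_idx, drop = FALSE]
  }
  if (!is.null(line_idx)) {
    if (is.character(line_idx))
      line_idx <- match(line_idx, lines)
    lines <- lines[line_idx]
    g <- g[line_idx, , drop = FALSE]
  }
  panel_genotypes(lines, v, g)
}

#' Construct a gene annotation collection
#'
#' Gene models on 1-based inclusive coordinates: every gene has a span and
#' at least one exon; UTR intervals are sub-intervals of exons; introns are
#' derivable as the gene span minus its exons (see [annotation_introns()]).
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (`+`/`-`).
#' @param exons data frame with columns `gene_id`, `start`, `end`.
#' @param utrs data frame with columns `gene_id`, `start`, `end`, `side`
#'   (`five_prime` or `three_prime`); may be empty.
#' @return an object of class `gene_annotation`.
#' @export
gene_annotation <- function(genes, exons,
                            utrs = data.frame(gene_id = character(),
                                              start = integer(),
                                              end = integer(),
                                              side = character())) {
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id", call. = FALSE)
  if (any(genes$end < genes$start))
    stop("gene end < start", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  no_exon <- setdiff(genes$gene_id, exons$gene_id)
  if (length(no_exon))
    stop("gene(s) without exons rejected: ",
         paste(no_exon, collapse = ", "), call. = FALSE)
  for (feat in list(exons, utrs)) {
    if (!nrow(feat)) next
    i <- match(feat$gene_id, genes$gene_id)
    if (anyNA(i))
      stop("feature references unknown gene_id", call. = FALSE)
    out <- feat$start < genes$start[i] | feat$end > genes$end[i]
    if (any(out))
      stop("child feature outside parent gene span for gene(s): ",
           paste(unique(feat$gene_id[out]), collapse = ", "), call. = FALSE)
  }
  genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- rownames(exons) <- NULL
  if (nrow(utrs)) rownames(utrs) <- NULL
  structure(list(genes = genes, exons = exons, utrs = utrs),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d exons, %d UTRs on %s\n",
              nrow(x$genes), nrow(x$exons), nrow(x$utrs),
              paste(unique(x$genes$chrom), collapse = ",")))
  invisible(x)
}

#' Derive intron intervals from a gene annotation
#'
#' Introns are the 1-based inclusive intervals of each gene span not
#' covered by any of the gene's exons.
#'
#' @param annot a `gene_annotation` object.
#' @return data frame with columns `gene_id`, `start`, `end`.
#' @export
annotation_introns <- function(annot) {
  out <- lapply(seq_len(nrow(annot$genes)), function(i) {
    g <- annot$genes[i, ]
    ex <- annot$exons[annot$exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    # merge overlapping/adjacent exons, then take complement within the span
    merged <- list()
    for (j in seq_len(nrow(ex))) {
      if (length(merged) && ex$start[j] <= merged[[length(merged)]][2] + 1L) {
        merged[[length(merged)]][2] <-
          max(merged[[length(merged)]][2], ex$end[j])
      } else {
        merged[[length(merged) + 1L]] <- c(ex$start[j], ex$end[j])
      }
    }
    gaps <- list()
    cur <- g$start
    for (m in merged) {
      if (m[1] > cur) gaps[[length(gaps) + 1L]] <- c(cur, m[1] - 1L)
      cur <- m[2] + 1L
    }
    if (cur <= g$end) gaps[[length(gaps) + 1L]] <- c(cur, g$end)
    if (!length(gaps)) return(NULL)
    data.frame(gene_id = g$gene_id,
               start = vapply(gaps, `[`, numeric(1), 1),
               end = vapply(gaps, `[`, numeric(1), 2))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene_id = character(), start = numeric(),
                      end = numeric())
  rownames(out) <- NULL
  out
}

#' Validate a per-individual phenotype table
#'
#' Columns: `line_id`, `sex`, `replicate`, `eye_area_px` (positive pixels).
#' The triple (line_id, sex, replicate) must be unique.
#'
#' @param pheno data frame.
#' @return the validated data frame (invisibly unchanged).
#' @export
validate_phenotypes <- function(pheno) {
  need <- c("line_id", "sex", "replicate", "eye_area_px")
  miss <- setdiff(need, names(pheno))
  if (length(miss))
    stop("phenotype table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(pheno$eye_area_px)) || any(pheno$eye_area_px <= 0))
    stop("eye_area_px must be positive and finite", call. = FALSE)
  key <- paste(pheno$line_id, pheno$sex, pheno$replicate, sep = "\r")
  if (anyDuplicated(key))
    stop("(line_id, sex, replicate) must be unique", call. = FALSE)
  invisible(pheno)
}
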
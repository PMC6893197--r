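# Readers and writers for the formats the screen touches: VCF 4.2 (GT
# only), genotype TSV, GFF3, GMT, phenotype CSV and the association TSV.
# Readers validate strictly and reject rather than repair; coordinates are
# 1-based inclusive throughout.

#' Write panel genotypes
#'
#' `format = "vcf"` emits a minimal VCF 4.2 with a single GT FORMAT field
#' (`0/0`, `1/1`, `./.`). `format = "tsv"` emits a lines x variants matrix
#' (values 0/2/NA) plus a companion `<stem>_variants.tsv` carrying the
#' variant metadata so that a read round-trips losslessly.
#'
#' @param geno a [panel_genotypes()] object.
#' @param path output file.
#' @param format `"vcf"` or `"tsv"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  if (format == "vcf") .write_vcf(geno, path) else .write_geno_tsv(geno, path)
  invisible(path)
}

.write_vcf <- function(geno, path) {
  v <- geno$variants
  gt <- matrix("./.", n_lines(geno), n_variants(geno))
  gt[!is.na(geno$geno) & geno$geno == 0] <- "0/0"
  gt[!is.na(geno$geno) & geno$geno == 2] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=modscreen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf("##contig=<ID=%s>", unique(v$chrom)),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$line_ids), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".", "PASS",
                ".", "GT", sep = "\t")
  body <- paste(body, apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
}

.write_geno_tsv <- function(geno, path) {
  mat <- as.data.frame(geno$geno)
  df <- cbind(data.frame(line_id = geno$line_ids, stringsAsFactors = FALSE),
              mat)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  meta <- paste0(tools::file_path_sans_ext(path), "_variants.tsv")
  utils::write.table(geno$variants, meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read panel genotypes from VCF or TSV
#'
#' Calls are recoded to the homozygous 0/2/NA convention. Heterozygous
#' calls are handled per `het_policy`: `"missing"` (default) converts them
#' to NA and reports the count in a warning; `"error"` aborts. Multi-allelic
#' records are preserved as-is ([filter_variants()] removes them later).
#'
#' @param path input file.
#' @param format `"vcf"`, `"tsv"` or `"auto"` (guess from extension).
#' @param het_policy `"missing"` or `"error"`.
#' @return a [panel_genotypes()] object.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           het_policy = c("missing", "error")) {
  format <- match.arg(format)
  het_policy <- match.arg(het_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "vcf") .read_vcf(path, het_policy)
  else .read_geno_tsv(path, het_policy)
}

.recode_gt <- function(gt, het_policy, where) {
  gt[is.na(gt)] <- "./."
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_real_, length(gt))
  a <- strsplit(gt, "/", fixed = TRUE)
  a1 <- vapply(a, `[`, "", 1L)
  a2 <- vapply(a, function(x) if (length(x) >= 2L) x[2L] else x[1L], "")
  missing <- a1 == "." | a2 == "."
  hom_ref <- !missing & a1 == "0" & a2 == "0"
  hom_alt <- !missing & a1 == a2 & a1 != "0"
  het <- !missing & !hom_ref & !hom_alt
  out[hom_ref] <- 0
  out[hom_alt] <- 2
  if (any(het)) {
    if (het_policy == "error")
      stop("heterozygous call(s) in ", where, "; het_policy = 'error'",
           call. = FALSE)
    warning(sum(het), " heterozygous call(s) in ", where,
            " treated as missing", call. = FALSE)
  }
  out
}

.read_vcf <- function(path, het_policy) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ids <- fix[, "ID"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- sprintf("%s_%s_SNP", fix[no_id, "CHROM"], fix[no_id, "POS"])
  if (anyDuplicated(ids))
    stop("duplicate variant id in VCF: ",
         ids[duplicated(ids)][1], call. = FALSE)
  variants <- data.frame(variant_id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field: ", path, call. = FALSE)
  calls <- matrix(.recode_gt(as.vector(gt), het_policy, path),
                  nrow(gt), ncol(gt))
  panel_genotypes(colnames(gt), variants, t(calls))
}

.read_geno_tsv <- function(path, het_policy) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"line_id" %in% names(df))
    stop("genotype TSV must have a line_id column: ", path, call. = FALSE)
  mat <- as.matrix(df[, setdiff(names(df), "line_id"), drop = FALSE])
  mode(mat) <- "numeric"
  bad <- !(mat %in% c(0, 2)) & !is.na(mat)
  dim(bad) <- dim(mat)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid genotype code at data row ", w[1], ", column ",
         colnames(mat)[w[2]], " of ", path, call. = FALSE)
  }
  meta <- paste0(tools::file_path_sans_ext(path), "_variants.tsv")
  if (file.exists(meta)) {
    variants <- utils::read.delim(meta, stringsAsFactors = FALSE)
    if (!identical(variants$variant_id, colnames(mat)))
      stop("variant metadata does not match genotype columns: ", meta,
           call. = FALSE)
  } else {
    warning("no variant metadata file (", meta, "); using placeholders",
            call. = FALSE)
    variants <- data.frame(variant_id = colnames(mat), chrom = "un",
                           pos = seq_len(ncol(mat)), ref = "N", alt = "N",
                           stringsAsFactors = FALSE)
  }
  panel_genotypes(df$line_id, variants, mat)
}

#' Write a gene annotation as GFF3
#'
#' Emits one `gene` record per gene (`ID=<gene_id>`), child `exon` records
#' and `five_prime_UTR`/`three_prime_UTR` records (`Parent=<gene_id>`).
#' Output is deterministic: features are ordered by gene, then exons, then
#' UTRs, each by start coordinate.
#'
#' @param annot a [gene_annotation()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annot, path) {
  fmt <- function(chrom, type, start, end, strand, attrs)
    paste(chrom, "modscreen", type, start, end, ".", strand, ".", attrs,
          sep = "\t")
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(annot$genes))) {
    g <- annot$genes[i, ]
    lines <- c(lines, fmt(g$chrom, "gene", g$start, g$end, g$strand,
                          sprintf("ID=%s", g$gene_id)))
    ex <- annot$exons[annot$exons$gene_id == g$gene_id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    for (j in seq_len(nrow(ex)))
      lines <- c(lines, fmt(g$chrom, "exon", ex$start[j], ex$end[j],
                            g$strand,
                            sprintf("ID=%s.e%d;Parent=%s", g$gene_id, j,
                                    g$gene_id)))
    ut <- annot$utrs[annot$utrs$gene_id == g$gene_id, , drop = FALSE]
    ut <- ut[order(ut$start), , drop = FALSE]
    for (j in seq_len(nrow(ut)))
      lines <- c(lines, fmt(g$chrom, paste0(ut$side[j], "_UTR"),
                            ut$start[j], ut$end[j], g$strand,
                            sprintf("ID=%s.u%d;Parent=%s", g$gene_id, j,
                                    g$gene_id)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects `gene` features with `ID` attributes and child `exon` /
#' `five_prime_UTR` / `three_prime_UTR` features with `Parent` attributes.
#' Genes without exons and child features outside their parent span are
#' rejected. An empty file yields an empty collection with a warning.
#'
#' @param path GFF3 file.
#' @return a [gene_annotation()] object.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  if (!nrow(df)) {
    warning("empty annotation file: ", path, call. = FALSE)
    return(gene_annotation(
      genes = data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character()),
      exons = data.frame(gene_id = character(), start = integer(),
                         end = integer())))
  }
  parent1 <- function(p) vapply(p, function(x)
    if (length(x)) as.character(x[[1]]) else NA_character_, "")
  df$parent <- if ("Parent" %in% names(df)) parent1(df$Parent)
               else NA_character_
  genes_df <- df[df$type == "gene", , drop = FALSE]
  if (!nrow(genes_df))
    stop("no gene features in ", path, call. = FALSE)
  genes <- data.frame(gene_id = as.character(genes_df$ID),
                      chrom = as.character(genes_df$seqnames),
                      start = genes_df$start, end = genes_df$end,
                      strand = as.character(genes_df$strand),
                      stringsAsFactors = FALSE)
  ex_df <- df[df$type == "exon", , drop = FALSE]
  exons <- data.frame(gene_id = ex_df$parent, start = ex_df$start,
                      end = ex_df$end, stringsAsFactors = FALSE)
  ut_df <- df[df$type %in% c("five_prime_UTR", "three_prime_UTR"), ,
              drop = FALSE]
  utrs <- data.frame(gene_id = ut_df$parent, start = ut_df$start,
                     end = ut_df$end,
                     side = sub("_UTR$", "", as.character(ut_df$type)),
                     stringsAsFactors = FALSE)
  gene_annotation(genes, exons, utrs)
}

#' Read gene sets from a GMT file
#'
#' Each line is `set_id <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Lines with fewer than three fields are a parse error; duplicate genes
#' within a set are removed with a warning.
#'
#' @param path GMT file.
#' @return a `gene_sets` collection: named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("GMT parse error at line ", which(nf < 3)[1],
         ": fewer than 3 tab-separated fields", call. = FALSE)
  ids <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate set id in GMT: ", ids[duplicated(ids)][1],
         call. = FALSE)
  descs <- vapply(fields, `[`, "", 2L)
  sets <- lapply(seq_along(fields), function(i) {
    g <- fields[[i]][-(1:2)]
    if (anyDuplicated(g)) {
      warning("duplicate gene(s) in set ", ids[i], " deduplicated",
              call. = FALSE)
      g <- unique(g)
    }
    g
  })
  names(sets) <- ids
  structure(sets, descriptions = setNames(descs, ids), class = "gene_sets")
}

#' Write gene sets to a GMT file
#'
#' @param sets a `gene_sets` collection (or plain named list of character
#'   vectors).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  descs <- attr(sets, "descriptions")
  if (is.null(descs)) descs <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id)
    paste(c(id, descs[[id]], sets[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write per-individual phenotype tables (CSV)
#'
#' Columns: `line_id`, `sex`, `replicate`, `eye_area_px`. Validation is
#' strict (positive areas, unique (line_id, sex, replicate)).
#'
#' @param path CSV file.
#' @return `read_phenotypes`: the validated data frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(line_id = "character",
                                       sex = "character"))
  validate_phenotypes(df)
  df
}

#' @rdname read_phenotypes
#' @param pheno phenotype data frame.
#' @export
write_phenotypes <- function(pheno, path) {
  validate_phenotypes(pheno)
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.assoc_cols <- c("chrom", "pos", "variant_id", "n_obs", "af", "beta",
                 "se", "lambda_hat", "p_wald")

#' Write / read association results (TSV)
#'
#' Fixed column contract: chrom, pos, variant_id, n_obs, af, beta, se,
#' lambda_hat, p_wald. Numeric columns are written with 12 significant
#' digits so a write-read round trip is lossless at that precision.
#'
#' @param results association result data frame.
#' @param path TSV file.
#' @return `read_assoc_results`: the data frame with the fixed columns.
#' @export
write_assoc_results <- function(results, path) {
  miss <- setdiff(.assoc_cols, names(results))
  if (length(miss))
    stop("association results missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  out <- results[, .assoc_cols, drop = FALSE]
  for (col in c("af", "beta", "se", "lambda_hat", "p_wald"))
    out[[col]] <- sprintf("%.12g", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_assoc_results
#' @export
read_assoc_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(.assoc_cols, names(df))
  if (length(miss))
    stop("association file ", path, " missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df[, .assoc_cols, drop = FALSE]
}
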
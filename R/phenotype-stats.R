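# Strain-level phenotype statistics: summaries, the background-effect
# ANOVA and cross-model Pearson correlations.

#' Summarize phenotypes per strain
#'
#' One row per strain with the replicate count, mean, median and SD of the
#' measured eye areas. The GWA phenotype is the strain mean of females;
#' medians are carried along for range-style summaries.
#'
#' @param pheno per-individual phenotype table (see
#'   [validate_phenotypes()]).
#' @param sex_filter optional sex label; rows with a different sex are
#'   dropped before summarizing. Strains left with zero observations are
#'   dropped with a warning.
#' @return data frame with columns `line_id`, `n`, `mean_px`, `median_px`,
#'   `sd_px`, ordered by `line_id`.
#' @export
summarize_strains <- function(pheno, sex_filter = NULL) {
  validate_phenotypes(pheno)
  if (!nrow(pheno)) stop("empty phenotype table", call. = FALSE)
  all_lines <- unique(pheno$line_id)
  if (!is.null(sex_filter)) {
    pheno <- pheno[pheno$sex == sex_filter, , drop = FALSE]
    dropped <- setdiff(all_lines, unique(pheno$line_id))
    if (length(dropped))
      warning(length(dropped), " strain(s) with no ", sex_filter,
              " observations dropped", call. = FALSE)
    if (!nrow(pheno))
      stop("no observations left after sex filter", call. = FALSE)
  }
  sp <- split(pheno$eye_area_px, pheno$line_id)
  out <- data.frame(
    line_id = names(sp),
    n = vapply(sp, length, integer(1)),
    mean_px = vapply(sp, mean, numeric(1)),
    median_px = vapply(sp, median, numeric(1)),
    sd_px = vapply(sp, function(x)
      if (length(x) > 1L) sd(x) else NA_real_, numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$line_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-way ANOVA for a genetic-background effect on the phenotype
#'
#' Classical fixed-effects one-way ANOVA of the individual observations
#' grouped by strain: does genetic background affect eye size at all?
#'
#' @param pheno per-individual phenotype table.
#' @return list with `f_stat`, `df_between`, `df_within`, `p_value`.
#' @export
strain_effect_anova <- function(pheno) {
  validate_phenotypes(pheno)
  k <- length(unique(pheno$line_id))
  if (k < 2)
    stop("need >= 2 strains for a between-strain ANOVA", call. = FALSE)
  if (nrow(pheno) <= k)
    stop("need more observations than strains", call. = FALSE)
  fit <- aov(eye_area_px ~ factor(line_id), data = pheno)
  tab <- anova(fit)
  list(f_stat = tab$`F value`[1],
       df_between = tab$Df[1],
       df_within = tab$Df[2],
       p_value = tab$`Pr(>F)`[1])
}

#' Pearson correlation between strain summaries of two models
#'
#' Inner-joins two strain summaries on `line_id` and correlates the chosen
#' statistic (strain means by default) with a two-sided t-based p-value.
#' Strains present in only one table are dropped; the count is reported in
#' a message.
#'
#' @param a,b strain summary data frames from [summarize_strains()].
#' @param statistic `"mean"` or `"median"`.
#' @return list with `r`, `p_value`, `n_pairs`.
#' @export
correlate_strain_means <- function(a, b, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  col <- paste0(statistic, "_px")
  shared <- intersect(a$line_id, b$line_id)
  dropped <- length(unique(c(a$line_id, b$line_id))) - length(shared)
  if (length(shared) < 3)
    stop("need >= 3 shared strains; got ", length(shared), call. = FALSE)
  if (dropped > 0)
    message(dropped, " unmatched strain(s) dropped from the correlation")
  x <- a[[col]][match(shared, a$line_id)]
  y <- b[[col]][match(shared, b$line_id)]
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n_pairs = length(shared))
}

#' Published strain-mean eye-size extremes for the two apoptosis models
#'
#' The smallest and largest per-strain eye areas (pixels) reported for the
#' DGRP screens of GAL4-driven p53 and promoter-driven reaper
#' overexpression in the developing eye, with the strains attaining them.
#' These published endpoints are the inputs for the cross-model range
#' comparison computed by [eye_size_ranges()].
#'
#' @return data frame with columns `model`, `min_px`, `min_line`,
#'   `max_px`, `max_line`.
#' @export
published_eye_size_extremes <- function() {
  data.frame(
    model = c("GMR>p53", "GMR-rpr"),
    min_px = c(10542, 7957),
    min_line = c("RAL812", "RAL83"),
    max_px = c(17835, 16884),
    max_line = c("RAL374", "RAL304"),
    stringsAsFactors = FALSE)
}

#' Strain-range of eye size per model
#'
#' The phenotypic range (largest minus smallest strain summary, in pixels)
#' for each model in an extremes table such as
#' [published_eye_size_extremes()]. A wider range means the panel harbors
#' more modifier variation for that apoptosis model.
#'
#' @param extremes data frame with columns `model`, `min_px`, `max_px`.
#' @return named numeric vector of ranges in pixels.
#' @export
eye_size_ranges <- function(extremes = published_eye_size_extremes()) {
  setNames(extremes$max_px - extremes$min_px, extremes$model)
}
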
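# Dunnett many-to-one comparisons for knockdown validation: each
# treatment group against the shared control, with family-wise two-sided
# adjusted p-values from the joint null of the correlated t statistics.

#' Dunnett's many-to-one multiple comparisons test
#'
#' Pooled-variance t statistics compare each treatment group with the
#' shared control. The family-wise adjusted two-sided p-value for
#' comparison j is `P(max_i |T_i| >= |t_j|)` under the joint null of the
#' k correlated t statistics (correlation `lambda_i * lambda_j` with
#' `lambda_i = sqrt((1/n0) / (1/n_i + 1/n0))`, induced by the shared
#' control and valid for unbalanced group sizes). The joint tail is
#' evaluated by seeded Monte Carlo on the multivariate t (shared
#' chi-square denominator), with the add-one convention so p lies in
#' (0, 1]; with the default 200000 draws the Monte-Carlo error is well
#' below 0.002.
#'
#' @param groups per-individual phenotype table (line_id identifies the
#'   group).
#' @param control_id group id of the shared control.
#' @param alpha family-wise significance level used to call direction.
#' @param n_mc Monte-Carlo draws for the joint null.
#' @param seed integer seed for the draws.
#' @return data frame with one row per treatment group: `group_id`, `n`,
#'   `mean_diff` (treatment minus control, px), `t_stat`, `p_adjusted`,
#'   `direction` (`enhancer` = significantly smaller eye, `suppressor` =
#'   significantly larger, `ns` otherwise).
#' @export
dunnett_test <- function(groups, control_id, alpha = 0.05,
                         n_mc = 200000, seed = 1L) {
  validate_phenotypes(groups)
  ids <- unique(groups$line_id)
  if (!control_id %in% ids)
    stop("control group '", control_id, "' not found", call. = FALSE)
  treat <- setdiff(ids, control_id)
  if (!length(treat))
    stop("need at least one treatment group", call. = FALSE)
  sp <- split(groups$eye_area_px, groups$line_id)
  ns <- vapply(sp, length, integer(1))
  if (any(ns < 2))
    stop("every group needs n >= 2", call. = FALSE)
  means <- vapply(sp, mean, numeric(1))
  ss <- vapply(sp, function(x) sum((x - mean(x))^2), numeric(1))
  nu <- sum(ns) - length(ns)
  s2 <- sum(ss) / nu
  if (s2 <= 0)
    stop("zero pooled variance; test undefined", call. = FALSE)
  n0 <- ns[[control_id]]
  k <- length(treat)
  diffs <- means[treat] - means[[control_id]]
  sed <- sqrt(s2 * (1 / ns[treat] + 1 / n0))
  t_stat <- diffs / sed
  lam <- sqrt((1 / n0) / (1 / ns[treat] + 1 / n0))
  maxabs <- withr::with_seed(as.integer(seed), {
    z0 <- rnorm(n_mc)
    denom <- sqrt(rchisq(n_mc, nu) / nu)
    mx <- rep(0, n_mc)
    for (j in seq_len(k)) {
      tj <- abs(lam[j] * z0 +
                  sqrt(1 - lam[j]^2) * rnorm(n_mc)) / denom
      mx <- pmax(mx, tj)
    }
    mx
  })
  p_adj <- vapply(abs(t_stat), function(tt)
    (1 + sum(maxabs >= tt)) / (1 + n_mc), numeric(1))
  direction <- ifelse(p_adj >= alpha, "ns",
                      ifelse(diffs < 0, "enhancer", "suppressor"))
  data.frame(group_id = treat, n = as.integer(ns[treat]),
             mean_diff = unname(diffs), t_stat = unname(t_stat),
             p_adjusted = unname(p_adj), direction = unname(direction),
             row.names = NULL, stringsAsFactors = FALSE)
}
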
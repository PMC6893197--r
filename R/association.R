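# Per-variant linear mixed-model association for an inbred panel:
# variant filters, the centered genetic relatedness matrix, profiled
# maximum likelihood over the variance ratio lambda, Wald tests, and
# QQ / genomic-inflation diagnostics.
#
# Model: y = a*1 + x*b + u + e,  u ~ MVN(0, lambda/tau * K),
#        e ~ MVN(0, (1/tau) * I).
# With K = U D U', rotating by U' whitens the covariance to
# diag(lambda*d_i + 1) / tau, so for a candidate lambda the fit is a
# weighted least squares with weights 1/(lambda*d_i + 1) and tau profiles
# out analytically. lambda is maximized on log10 scale by a coarse grid
# followed by Brent refinement.

#' Filter variants for association
#'
#' Retains variants that are biallelic, have a missing-call fraction at
#' most `max_missing`, and a sample minor allele frequency (computed over
#' non-missing calls) of at least `maf_min`. Counts removed per criterion
#' are reported in a message and attached as attribute `"removed"`.
#'
#' @param geno a [panel_genotypes()] object.
#' @param maf_min minimum sample MAF (inclusive), default 0.05.
#' @param max_missing maximum missing fraction (inclusive), default 0.20.
#' @return the filtered [panel_genotypes()] object.
#' @export
filter_variants <- function(geno, maf_min = 0.05, max_missing = 0.20) {
  g <- geno$geno
  biallelic <- !grepl(",", geno$variants$alt, fixed = TRUE)
  miss_frac <- colMeans(is.na(g))
  af <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0          # all calls missing
  keep <- biallelic & miss_frac <= max_missing & maf >= maf_min
  removed <- c(non_biallelic = sum(!biallelic),
               missingness = sum(biallelic & miss_frac > max_missing),
               maf = sum(biallelic & miss_frac <= max_missing &
                           maf < maf_min))
  message(sprintf(
    "filter_variants: kept %d/%d (removed %d non-biallelic, %d by missingness, %d by MAF < %g)",
    sum(keep), length(keep), removed[1], removed[2], removed[3], maf_min))
  if (!sum(keep)) warning("no variants pass the filters", call. = FALSE)
  out <- subset_panel(geno, variant_idx = which(keep))
  attr(out, "removed") <- removed
  out
}

#' Centered genetic relatedness matrix
#'
#' `K = (1/p) * sum_k (x_k - xbar_k 1)(x_k - xbar_k 1)'` over the p
#' variants of the panel, with missing calls imputed to the variant mean
#' before centering. This is the marker-based kinship used as the
#' random-effect covariance of the mixed model; monomorphic variants
#' contribute exactly zero.
#'
#' @param geno a [panel_genotypes()] object.
#' @return list of class `relatedness_matrix` with elements `line_ids` and
#'   `K` (n x n, dimnames set to the line ids).
#' @export
compute_grm <- function(geno) {
  X <- geno$geno
  p <- ncol(X)
  if (!p) stop("no variants", call. = FALSE)
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(p)) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mu[j]
  }
  Xc <- sweep(X, 2L, mu, `-`)
  if (all(abs(Xc) < 1e-12))
    stop("all variants are monomorphic; relatedness undefined",
         call. = FALSE)
  K <- tcrossprod(Xc) / p
  dimnames(K) <- list(geno$line_ids, geno$line_ids)
  structure(list(line_ids = geno$line_ids, K = K),
            class = "relatedness_matrix")
}

# Eigendecomposition of K, reused across the scan. Small negative
# eigenvalues from round-off are clamped to zero; a genuinely indefinite
# matrix is rejected.
lmm_eigen <- function(K) {
  if (inherits(K, "relatedness_matrix")) K <- K$K
  if (max(abs(K - t(K))) > 1e-10)
    stop("relatedness matrix is not symmetric", call. = FALSE)
  e <- eigen(K, symmetric = TRUE)
  tr <- sum(diag(K))
  if (min(e$values) < -1e-8 * tr)
    stop("relatedness matrix is not positive semidefinite", call. = FALSE)
  e$values <- pmax(e$values, 0)
  e
}

# Profile log-likelihood (and fit) at a fixed lambda, in the rotated
# basis. ot/yt/gt are U' %*% (1, y, x); precomputed products keep each
# evaluation O(n).
.lmm_eval <- function(lambda, d, ot, yt, gt, reml = FALSE,
                      coefs = FALSE) {
  n <- length(d)
  w <- 1 / (lambda * d + 1)
  a11 <- sum(w * ot * ot)
  a12 <- sum(w * ot * gt)
  a22 <- sum(w * gt * gt)
  b1 <- sum(w * ot * yt)
  b2 <- sum(w * gt * yt)
  syy <- sum(w * yt * yt)
  det <- a11 * a22 - a12 * a12
  if (det <= 0) return(list(ll = -Inf))
  beta <- (a11 * b2 - a12 * b1) / det
  alpha <- (a22 * b1 - a12 * b2) / det
  rss <- syy - (alpha * b1 + beta * b2)
  rss <- max(rss, 1e-300)
  sumlog <- sum(log1p(lambda * d))
  if (reml) {
    # restricted likelihood; the lambda-free log det(X'X) term is dropped
    nf <- n - 2L
    tau_inv <- rss / nf
    ll <- -0.5 * (nf * log(2 * pi * tau_inv) + nf + sumlog + log(det))
  } else {
    tau_inv <- rss / n
    ll <- -0.5 * (n * log(2 * pi * tau_inv) + n + sumlog)
  }
  if (!coefs) return(list(ll = ll))
  list(ll = ll, beta = beta, alpha = alpha, rss = rss,
       tau_inv = tau_inv, var_beta_unit = a11 / det)
}

#' Fit the linear mixed model for one variant
#'
#' Maximizes the profiled likelihood of
#' `y = a + x b + u + e`, `u ~ MVN(0, lambda/tau K)`, over
#' `log10(lambda) in [-5, 5]` (21-point grid, then Brent to 1e-6 relative
#' tolerance; the lambda = 0 boundary is always a candidate), then reports
#' the Wald test of `b = 0` against chi-square(1).
#'
#' @param y named (or aligned) numeric vector of strain means.
#' @param x numeric genotype vector coded 0/2; missing calls are imputed
#'   to the mean.
#' @param K relatedness matrix (matrix or [compute_grm()] result); ignored
#'   when `eig` is given.
#' @param eig optional precomputed [eigen()] of K (reused across a scan).
#' @param lambda optional fixed lambda; skips the likelihood search
#'   (`lambda = 0` reproduces ordinary least squares exactly).
#' @param method `"ML"` (default, matching the usual mixed-model GWAS
#'   convention) or `"REML"`.
#' @return list with `beta`, `se`, `lambda_hat`, `p_wald`, `alpha`,
#'   `tau_inv`, `loglik`, `n_obs`, `af`.
#' @export
fit_lmm_variant <- function(y, x, K = NULL, eig = NULL, lambda = NULL,
                            method = c("ML", "REML")) {
  method <- match.arg(method)
  reml <- method == "REML"
  if (anyNA(y)) stop("y must not contain NA", call. = FALSE)
  if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
  n <- length(y)
  if (length(x) != n) stop("y and x lengths differ", call. = FALSE)
  if (var(x) == 0)
    stop("degenerate variant: genotype is constant", call. = FALSE)
  if (is.null(eig)) {
    if (is.null(K)) stop("supply K or eig", call. = FALSE)
    eig <- lmm_eigen(K)
  }
  d <- eig$values
  U <- eig$vectors
  ot <- drop(crossprod(U, rep(1, n)))
  yt <- drop(crossprod(U, y))
  gt <- drop(crossprod(U, x))
  fit <- .lmm_fit_rotated(d, ot, yt, gt, lambda, reml)
  z2 <- (fit$beta / fit$se)^2
  c(fit[c("beta", "se", "lambda_hat", "alpha", "tau_inv", "loglik")],
    list(p_wald = pchisq(z2, df = 1, lower.tail = FALSE),
         n_obs = n, af = mean(x) / 2))
}

# Core optimizer on rotated inputs (shared by fit_lmm_variant/run_gwas).
.lmm_fit_rotated <- function(d, ot, yt, gt, lambda = NULL, reml = FALSE) {
  obj <- function(l10) .lmm_eval(10^l10, d, ot, yt, gt, reml)$ll
  if (is.null(lambda)) {
    grid <- seq(-5, 5, length.out = 21)
    ll_grid <- vapply(grid, obj, numeric(1))
    ll0 <- .lmm_eval(0, d, ot, yt, gt, reml)$ll
    i <- which.max(ll_grid)
    lo <- grid[max(i - 1L, 1L)]
    hi <- grid[min(i + 1L, length(grid))]
    opt <- optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-6)
    best <- max(ll_grid[i], opt$objective)
    lambda <- if (ll0 >= best) 0 else
      if (opt$objective >= ll_grid[i]) 10^opt$maximum else 10^grid[i]
  }
  f <- .lmm_eval(lambda, d, ot, yt, gt, reml, coefs = TRUE)
  se <- sqrt(f$tau_inv * f$var_beta_unit)
  list(beta = f$beta, se = se, lambda_hat = lambda, alpha = f$alpha,
       tau_inv = f$tau_inv, loglik = f$ll)
}

#' Genome-wide association scan
#'
#' Joins strain summaries with the genotype panel on `line_id`, builds (or
#' subsets) the relatedness matrix, and fits the mixed model once per
#' variant. The phenotype is the strain mean (`statistic = "mean"`).
#' Missing genotypes are imputed to the variant mean; variants that are
#' constant across the joined lines are dropped with a warning.
#'
#' @param pheno strain summary from [summarize_strains()].
#' @param geno a filtered [panel_genotypes()] object.
#' @param K optional [compute_grm()] result or matrix with line-id
#'   dimnames; computed from `geno` (after the join) when omitted.
#' @param statistic strain statistic regressed on the genotypes.
#' @param min_lines refuse to run below this many joined lines
#'   (underpowered), default 30.
#' @param method `"ML"` or `"REML"`.
#' @return data frame with columns chrom, pos, variant_id, n_obs, af,
#'   beta, se, lambda_hat, p_wald (one row per retained variant).
#' @export
run_gwas <- function(pheno, geno, K = NULL,
                     statistic = c("mean", "median"),
                     min_lines = 30, method = c("ML", "REML")) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  y_all <- setNames(pheno[[paste0(statistic, "_px")]], pheno$line_id)
  common <- intersect(geno$line_ids, names(y_all))
  if (length(common) < min_lines)
    stop("only ", length(common), " lines shared between phenotypes and ",
         "genotypes (< ", min_lines, "); refusing to run", call. = FALSE)
  geno <- subset_panel(geno, line_idx = common)
  y <- unname(y_all[common])
  if (is.null(K)) {
    K <- compute_grm(geno)$K
  } else {
    if (inherits(K, "relatedness_matrix")) K <- K$K
    if (is.null(rownames(K)) || !all(common %in% rownames(K)))
      stop("K lacks the joined line ids", call. = FALSE)
    K <- K[common, common]
  }
  eig <- lmm_eigen(K)
  d <- eig$values
  U <- eig$vectors
  n <- length(y)
  X <- geno$geno
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- mu[j]
  }
  keep <- apply(X, 2L, var) > 0
  if (any(!keep))
    warning(sum(!keep), " variant(s) constant across joined lines dropped",
            call. = FALSE)
  X <- X[, keep, drop = FALSE]
  v <- geno$variants[keep, , drop = FALSE]
  ot <- drop(crossprod(U, rep(1, n)))
  yt <- drop(crossprod(U, y))
  Gt <- crossprod(U, X)
  reml <- method == "REML"
  p <- ncol(X)
  beta <- se <- lam <- numeric(p)
  for (j in seq_len(p)) {
    f <- .lmm_fit_rotated(d, ot, yt, Gt[, j], reml = reml)
    beta[j] <- f$beta; se[j] <- f$se; lam[j] <- f$lambda_hat
  }
  data.frame(chrom = v$chrom, pos = v$pos, variant_id = v$variant_id,
             n_obs = n, af = colMeans(X) / 2, beta = beta, se = se,
             lambda_hat = lam,
             p_wald = pchisq((beta / se)^2, df = 1, lower.tail = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' QQ data and genomic-inflation factor for an association scan
#'
#' Sorted observed -log10 p-values against uniform expected quantiles
#' `i/(m+1)`, plus the genomic-control inflation factor
#' `lambda_GC = median(qchisq(1 - p, 1)) / 0.4549364`, the ratio of the
#' median association chi-square to its null median. Well-calibrated scans
#' give lambda_GC near 1.
#'
#' @param results association data frame (needs `p_wald`) or a bare
#'   numeric vector of p-values.
#' @return list of class `qq_diagnostics` with `expected`, `observed`
#'   (-log10 scales, ascending expected) and `lambda_gc`.
#' @export
qq_diagnostics <- function(results) {
  p <- if (is.data.frame(results)) results$p_wald else as.numeric(results)
  if (length(p) < 10)
    stop("need >= 10 p-values for QQ diagnostics", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  m <- length(p)
  obs <- sort(p)
  expd <- seq_len(m) / (m + 1)
  lambda_gc <- median(qchisq(obs, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1, lower.tail = FALSE)
  structure(list(expected = -log10(expd), observed = -log10(obs),
                 lambda_gc = lambda_gc),
            class = "qq_diagnostics")
}

#' @export
print.qq_diagnostics <- function(x, ...) {
  cat(sprintf("qq_diagnostics: %d p-values, lambda_GC = %.3f\n",
              length(x$observed), x$lambda_gc))
  invisible(x)
}
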
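# Variant filters, the centered GRM, and the per-variant linear mixed
# model against dense-matrix oracles.

test_that("variant filters enforce MAF, missingness and biallelism", {
  # 200 lines; 9 carriers = MAF 0.045 removed, 10 carriers = 0.05 kept
  m <- matrix(0, 200, 2)
  m[1:9, 1] <- 2
  m[1:10, 2] <- 2
  g <- tiny_panel(m)
  kept <- suppressMessages(filter_variants(g))
  expect_equal(kept$variants$variant_id, "v002")

  # 2 alt alleles => removed regardless of frequency
  g2 <- tiny_panel(matrix(c(0, 2, 2, 0, 2, 0), nrow = 3))
  g2$variants$alt[1] <- "T,C"
  kept2 <- suppressMessages(filter_variants(g2))
  expect_equal(kept2$variants$variant_id, c("v002"))

  # missingness threshold is inclusive
  m3 <- matrix(rep(c(0, 2), 5), 10, 3)
  m3[1:2, 2] <- NA   # 20% missing: kept
  m3[1:3, 3] <- NA   # 30% missing: removed
  kept3 <- suppressMessages(filter_variants(tiny_panel(m3),
                                            max_missing = 0.2))
  expect_setequal(kept3$variants$variant_id, c("v001", "v002"))
})

test_that("random panels are filtered identically to a brute-force oracle", {
  cfg <- small_cfg(n_variants = 1000L, missing_rate = 0.05,
                   maf_range = c(0.01, 0.5), seed = 31L)
  g <- simulate_genotypes(cfg)
  kept <- suppressMessages(filter_variants(g, 0.05, 0.2))
  oracle <- vapply(seq_len(n_variants(g)), function(j) {
    x <- g$geno[, j]
    obs <- x[!is.na(x)]
    if (mean(is.na(x)) > 0.2) return(FALSE)
    f <- sum(obs) / (2 * length(obs))
    min(f, 1 - f) >= 0.05
  }, logical(1))
  expect_equal(kept$variants$variant_id, g$variants$variant_id[oracle])
})

test_that("GRM matches the hand-computed 3x2 example to 1e-12", {
  g <- tiny_panel(matrix(c(0, 2, 2,
                           2, 0, 2), nrow = 3))
  K <- compute_grm(g)$K
  K_hand <- matrix(c(10, -8, -2,
                     -8, 10, -2,
                     -2, -2, 4) / 9, 3, 3,
                   dimnames = list(g$line_ids, g$line_ids))
  expect_equal(K, K_hand, tolerance = 1e-12)
})

test_that("GRM: monomorphic variants contribute zero; symmetry and PSD hold", {
  g2 <- tiny_panel(matrix(c(0, 2, 2,
                            2, 0, 2,
                            2, 2, 2), nrow = 3))   # third is monomorphic
  # p = 3 variants in the denominator, but column 3 adds nothing
  K2 <- compute_grm(g2)$K
  K_hand <- matrix(c(10, -8, -2,
                     -8, 10, -2,
                     -2, -2, 4) / 9, 3, 3) * (2 / 3)
  expect_equal(unname(K2), K_hand, tolerance = 1e-12)

  cfg <- small_cfg(missing_rate = 0.1)
  K <- compute_grm(simulate_genotypes(cfg))$K
  expect_lt(max(abs(K - t(K))), 1e-10)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * sum(diag(K)))

  mono <- tiny_panel(matrix(2, 4, 3))
  expect_error(compute_grm(mono), "monomorphic")
})

test_that("with K = I the mixed model collapses to ordinary least squares", {
  set.seed(42)
  n <- 40
  x <- sample(c(0, 2), n, replace = TRUE)
  y <- 14000 + 150 * x + rnorm(n, 0, 300)
  f <- fit_lmm_variant(y, x, K = diag(n))
  ols <- lm(y ~ x)
  expect_equal(f$beta, unname(coef(ols)[2]), tolerance = 1e-8)
  expect_equal(f$alpha, unname(coef(ols)[1]), tolerance = 1e-8)
  # ML variance uses n, OLS uses n - 2; p is chi-square rather than t
  se_ols <- summary(ols)$coefficients[2, 2]
  expect_equal(f$se, se_ols * sqrt((n - 2) / n), tolerance = 1e-6)
})

test_that("beta at fixed lambda equals the dense GLS oracle", {
  set.seed(7)
  n <- 6
  Z <- matrix(rnorm(n * 4), n, 4)
  K <- tcrossprod(Z) / 4
  x <- c(0, 0, 2, 2, 0, 2)
  y <- 100 + 50 * x + drop(chol(K + diag(0.01, n)) %*% rnorm(n))
  lam <- 2
  f <- fit_lmm_variant(y, x, K = K, lambda = lam)
  V <- lam * K + diag(n)
  X <- cbind(1, x)
  Vi <- solve(V)
  coef_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  expect_equal(f$beta, coef_gls[2], tolerance = 1e-10)
  expect_equal(f$alpha, coef_gls[1], tolerance = 1e-10)
  # se from the oracle: tau_hat * (X' V^-1 X)^-1 [2,2], tau_hat = RSS_V / n
  r <- y - X %*% coef_gls
  tau_hat <- drop(t(r) %*% Vi %*% r) / n
  se_or <- sqrt(tau_hat * solve(t(X) %*% Vi %*% X)[2, 2])
  expect_equal(f$se, se_or, tolerance = 1e-10)

  # lambda fixed to 0 is exactly OLS (analytic limit)
  f0 <- fit_lmm_variant(y, x, K = K, lambda = 0)
  expect_equal(f0$beta, unname(coef(lm(y ~ x))[2]), tolerance = 1e-12)
})

test_that("fit is equivariant under coding flips and phenotype shifts", {
  b <- sim_bundle(small_cfg(missing_rate = 0))
  K <- compute_grm(b$geno)
  s <- summarize_strains(b$pheno)
  y <- s$mean_px[match(b$geno$line_ids, s$line_id)]
  x <- b$geno$geno[, 5]
  f <- fit_lmm_variant(y, x, K = K$K)
  # the profile likelihood is nearly flat in lambda, so equivariance holds
  # to the refit jitter of the lambda search, not to machine precision
  flip <- fit_lmm_variant(y, 2 - x, K = K$K)
  expect_equal(flip$beta, -f$beta, tolerance = 1e-2)
  expect_equal(flip$p_wald, f$p_wald, tolerance = 1e-2)
  shift <- fit_lmm_variant(y + 5000, x, K = K$K)
  expect_equal(shift$beta, f$beta, tolerance = 1e-6)
  expect_equal(shift$alpha, f$alpha + 5000, tolerance = 1e-4)
  expect_error(fit_lmm_variant(y, rep(2, length(y)), K = K$K),
               "degenerate")
})

test_that("run_gwas recovers a strong planted variant and is deterministic", {
  cfg <- small_cfg(n_causal = 1L, causal_effect_size = 800,
                   replicate_sd = 100, lambda_true = 0.2,
                   missing_rate = 0)
  b <- sim_bundle(cfg)
  s <- summarize_strains(b$pheno)
  fg <- suppressMessages(filter_variants(b$geno))
  a <- run_gwas(s, fg)
  expect_equal(a$variant_id[which.min(a$p_wald)],
               b$truth$causal_variant_ids)
  # bit-identical on rerun
  expect_identical(a, run_gwas(s, fg))
  # agrees with the single-variant interface
  K <- compute_grm(fg)
  y <- s$mean_px[match(fg$line_ids, s$line_id)]
  j <- which(fg$variants$variant_id == b$truth$causal_variant_ids)
  f1 <- fit_lmm_variant(y, fg$geno[, j], K = K$K)
  row <- a[a$variant_id == b$truth$causal_variant_ids, ]
  expect_equal(row$beta, f1$beta, tolerance = 1e-5)
  expect_equal(row$p_wald, f1$p_wald, tolerance = 1e-5)
})

test_that("jointly permuting lines in y, genotypes and K changes nothing", {
  b <- sim_bundle(small_cfg(missing_rate = 0))
  s <- summarize_strains(b$pheno)
  fg <- suppressMessages(filter_variants(b$geno))
  a <- run_gwas(s, fg)
  perm <- sample(length(fg$line_ids))
  fg_p <- subset_panel(fg, line_idx = perm)
  a_p <- run_gwas(s, fg_p)
  expect_equal(a_p$beta, a$beta, tolerance = 1e-3)
  expect_equal(a_p$p_wald, a$p_wald, tolerance = 1e-3)
  # too few joined lines is refused
  expect_error(run_gwas(s[1:10, ], fg), "refusing")
})

test_that("QQ diagnostics: calibrated grid gives lambda_GC = 1, inflation is detected", {
  m <- 5000
  p_grid <- seq_len(m) / (m + 1)
  q <- qq_diagnostics(p_grid)
  expect_equal(q$lambda_gc, 1, tolerance = 0.02)
  expect_equal(length(q$expected), m)
  # chi-square values inflated by 1.5 before p conversion
  chi <- qchisq(p_grid, 1, lower.tail = FALSE)
  p_inf <- pchisq(1.5 * chi, 1, lower.tail = FALSE)
  expect_equal(qq_diagnostics(p_inf)$lambda_gc, 1.5, tolerance = 0.05)
  expect_error(qq_diagnostics(0.5), ">= 10")
})
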
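test_that("REML recovers null and non-null variance components", {
  set.seed(101)
  # white noise with A = I: variance goes to the residual, polygenic to zero
  n <- 1500
  vc <- estimate_null_variance_components(rnorm(n), rep(1, n), diag(n))
  expect_equal(vc$sigma2_u, 0)
  expect_equal(vc$sigma2_e, 1, tolerance = 0.08)

  # deep pedigree, sigma2_u = 2, sigma2_e = 1: recover within MC tolerance
  cfg <- small_config(n_founders = 80, n_generations = 4, sigma2_u = 2,
                      sigma2_e = 1, n_qtl = 0, qtl_variance_fraction = 0,
                      n_markers_per_chromosome = 5)
  est <- t(vapply(1:5, function(s) {
    cfg$seed <- 100 + s
    ped <- simulate_pedigree(cfg)
    A <- build_relationship_matrix(ped)
    gt <- simulate_genotypes(cfg, ped)
    ph <- simulate_phenotypes(cfg, gt$geno, A, gt$map)
    vc <- estimate_null_variance_components(ph$phenotypes$y_c,
                                            ph$phenotypes$weight, A)
    c(vc$sigma2_u, vc$sigma2_e)
  }, numeric(2)))
  expect_equal(mean(est[, 1]), 2, tolerance = 0.35)
  expect_equal(mean(est[, 2]), 1, tolerance = 0.2)

  expect_error(estimate_null_variance_components(rep(1, 10), rep(1, 10),
                                                 diag(10)), "constant")
})

test_that("the scan reduces exactly to OLS when sigma2_u = 0 and weights are 1", {
  set.seed(102)
  n <- 200; m <- 500
  X <- matrix(rbinom(n * m, 2, 0.3), n, m)
  y <- rnorm(n)
  vc0 <- structure(list(sigma2_u = 0, sigma2_e = 1, gamma = 0,
                        rotation = NULL), class = "qw_vc")
  fit <- lmm_gwas(y, X, diag(n), vc = vc0)
  xc <- X - rep(colMeans(X), each = n)
  sxx <- colSums(xc^2)
  b <- colSums(xc * (y - mean(y))) / sxx
  rss <- sum((y - mean(y))^2) - b^2 * sxx
  se <- sqrt(rss / (n - 2) / sxx)
  expect_lt(max(abs(fit$results$effect - b)), 1e-8)
  expect_lt(max(abs(fit$results$se - se)), 1e-8)
  expect_lt(max(abs(fit$results$t - b / se)), 1e-8)
  ols_p <- 2 * pt(abs(b / se), df = n - 2, lower.tail = FALSE)
  expect_lt(max(abs(fit$results$p - ols_p)), 1e-10)
})

test_that("duplicate markers give identical per-marker results", {
  set.seed(103)
  cfg <- small_config(seed = 16)
  d <- simulate_dataset(cfg)
  X <- impute_missing_naive(d$geno)
  X2 <- cbind(X, dup = X[, 7])
  fit <- lmm_gwas(d$phenotypes$y_c, X2, d$A, d$phenotypes$weight)
  last <- nrow(fit$results)
  for (col in c("effect", "se", "t", "p"))
    expect_equal(fit$results[[col]][last], fit$results[[col]][7])
})

test_that("t statistics are invariant to joint rescaling of weights and variances", {
  set.seed(104)
  cfg <- small_config(seed = 17)
  d <- simulate_dataset(cfg)
  X <- impute_missing_naive(d$geno)
  y <- d$phenotypes$y_c; w <- d$phenotypes$weight
  vc <- estimate_null_variance_components(y, w, d$A)
  fit1 <- lmm_gwas(y, X, d$A, w, vc = vc)
  # scaling weights and sigma2_e by the same factor leaves V untouched
  vc2 <- structure(list(sigma2_u = vc$sigma2_u, sigma2_e = 2 * vc$sigma2_e,
                        gamma = vc$gamma / 2, rotation = NULL), class = "qw_vc")
  fit2 <- lmm_gwas(y, X, d$A, 2 * w, vc = vc2)
  expect_equal(fit1$results$t, fit2$results$t, tolerance = 1e-8)
  # scaling the whole V by a constant is absorbed by the per-marker residual
  vc3 <- structure(list(sigma2_u = 3 * vc$sigma2_u, sigma2_e = 3 * vc$sigma2_e,
                        gamma = vc$gamma, rotation = NULL), class = "qw_vc")
  fit3 <- lmm_gwas(y, X, d$A, w, vc = vc3)
  expect_equal(fit1$results$t, fit3$results$t, tolerance = 1e-8)
})

test_that("scan results are invariant to marker and individual order", {
  set.seed(105)
  cfg <- small_config(seed = 18)
  d <- simulate_dataset(cfg)
  X <- impute_missing_naive(d$geno)
  y <- d$phenotypes$y_c; w <- d$phenotypes$weight
  fit <- lmm_gwas(y, X, d$A, w)
  pm <- sample(ncol(X))
  fit_m <- lmm_gwas(y, X[, pm], d$A, w)
  expect_equal(fit_m$results$t, fit$results$t[pm], tolerance = 1e-6)
  pi_ <- sample(nrow(X))
  fit_i <- lmm_gwas(y[pi_], X[pi_, ], d$A[pi_, pi_], w[pi_])
  expect_equal(fit_i$results$t, fit$results$t, tolerance = 1e-6)
})

test_that("monomorphic markers are flagged with p = 1", {
  set.seed(106)
  n <- 80
  X <- cbind(mono = rep(1L, n), poly = rbinom(n, 2, 0.4))
  fit <- lmm_gwas(rnorm(n), X, diag(n))
  expect_true(fit$results$monomorphic[1])
  expect_equal(fit$results$p[1], 1)
  expect_false(fit$results$monomorphic[2])
})

test_that("Bonferroni thresholds reproduce the published panel values", {
  expect_equal(round(bonferroni_threshold(37060, 0.05), 2), 5.87)
  expect_equal(round(bonferroni_threshold(37060, 0.01), 2), 6.57)
  expect_equal(round(bonferroni_threshold(36058, 0.05), 2), 5.86)
  expect_equal(round(bonferroni_threshold(36058, 0.01), 2), 6.56)
  expect_equal(bonferroni_threshold(1, 0.05), -log10(0.05))
})

test_that("genomic inflation lambda behaves at the reference points", {
  expect_equal(genomic_inflation_lambda(rep(0.5, 7)), 1)
  set.seed(107)
  expect_equal(genomic_inflation_lambda(runif(50000)), 1, tolerance = 0.02)
  expect_error(genomic_inflation_lambda(numeric(0)), "no p-values")
  expect_error(genomic_inflation_lambda(c(0.5, 0)), "0, 1")
})

test_that("unmodelled population stratification inflates lambda", {
  set.seed(108)
  n <- 400; m <- 1500
  grp <- rep(0:1, each = n / 2)
  p1 <- runif(m, 0.1, 0.9)
  p2 <- pmin(0.95, pmax(0.05, p1 + runif(m, -0.3, 0.3)))
  X <- vapply(seq_len(m), function(j)
    rbinom(n, 2, ifelse(grp == 0, p1[j], p2[j])), integer(n))
  y <- grp + rnorm(n)
  vc0 <- structure(list(sigma2_u = 0, sigma2_e = 1, gamma = 0,
                        rotation = NULL), class = "qw_vc")
  fit <- lmm_gwas(y, X, diag(n), vc = vc0)
  expect_gt(fit$lambda, 1.5)
})
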
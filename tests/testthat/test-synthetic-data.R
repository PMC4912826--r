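test_that("smallest pedigrees have the expected structure", {
  cfg <- sim_config(n_founders = 2, n_generations = 1,
                    offspring_per_mating = 1, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 3)
  expect_equal(sort(unlist(ped[3, c("sire", "dam")], use.names = FALSE)), c(1L, 2L))

  cfg0 <- sim_config(n_founders = 5, n_generations = 0, seed = 1)
  ped0 <- simulate_pedigree(cfg0)
  expect_equal(nrow(ped0), 5)
  expect_true(all(ped0$sire == 0L & ped0$dam == 0L))
})

test_that("simulation is deterministic given the seed", {
  cfg <- small_config(seed = 42)
  expect_identical(simulate_pedigree(cfg), simulate_pedigree(cfg))
  ped <- simulate_pedigree(cfg)
  g1 <- simulate_genotypes(cfg, ped)
  g2 <- simulate_genotypes(cfg, ped)
  expect_identical(g1, g2)
  A <- build_relationship_matrix(ped)
  p1 <- simulate_phenotypes(cfg, g1$geno, A, g1$map)
  p2 <- simulate_phenotypes(cfg, g2$geno, A, g2$map)
  expect_identical(p1, p2)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_founders = 0), "n_founders")
  expect_error(sim_config(ld_decay = 1.5), "ld_decay")
  expect_error(sim_config(weight_range = c(0, 1)), "weight_range")
  expect_error(sim_config(missing_rate = -0.1), "missing_rate")
  expect_error(sim_config(qtl_variance_fraction = 1), "qtl_variance_fraction")
})

test_that("relationship matrix follows the tabular method", {
  # trio: unrelated parents and one offspring
  trio <- data.frame(id = 1:3, sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L))
  A <- build_relationship_matrix(trio)
  expect_equal(unname(diag(A)), c(1, 1, 1))
  expect_equal(A[3, 1], 0.5)
  expect_equal(A[3, 2], 0.5)

  # two full sibs
  sibs <- data.frame(id = 1:4, sire = c(0L, 0L, 1L, 1L), dam = c(0L, 0L, 2L, 2L))
  expect_equal(build_relationship_matrix(sibs)[3, 4], 0.5)

  # offspring of a parent-offspring mating: a(1,3) = 0.5 so diagonal 1.25
  inc <- data.frame(id = 1:4, sire = c(0L, 0L, 1L, 1L), dam = c(0L, 0L, 2L, 3L))
  A4 <- build_relationship_matrix(inc)
  expect_equal(A4[4, 4], 1.25)

  # unordered pedigree is refused
  bad <- data.frame(id = 1:2, sire = c(2L, 0L), dam = c(0L, 0L))
  expect_error(build_relationship_matrix(bad), "ordered")
})

test_that("relationship matrices are symmetric PSD with diagonal >= 1", {
  for (s in 1:4) {
    ped <- simulate_pedigree(small_config(seed = s))
    A <- build_relationship_matrix(ped)
    expect_equal(A, t(A))
    expect_true(all(diag(A) >= 1))
    expect_silent(chol(A + 1e-10 * diag(nrow(A))))
  }
})

test_that("the sparse pedigree A-inverse inverts the tabular A", {
  # include an inbred mating so the inbreeding correction is exercised
  ped <- data.frame(id = 1:6, sire = c(0L, 0L, 1L, 1L, 3L, 4L),
                    dam = c(0L, 0L, 2L, 2L, 4L, 5L))
  A <- build_relationship_matrix(ped)
  Ai <- relationship_inverse(ped)
  expect_lt(max(abs(as.matrix(Ai %*% A) - diag(6))), 1e-10)

  ped2 <- simulate_pedigree(small_config(seed = 9))
  A2 <- build_relationship_matrix(ped2)
  Ai2 <- relationship_inverse(ped2)
  expect_lt(max(abs(as.matrix(Ai2 %*% A2) - diag(nrow(A2)))), 1e-8)
})

test_that("genotype simulation honours missingness and the LD model", {
  cfg <- small_config(seed = 3, missing_rate = 0)
  ped <- simulate_pedigree(cfg)
  gt <- simulate_genotypes(cfg, ped)
  st <- compute_marker_stats(gt$geno, gt$map)
  expect_true(all(st$call_frequency == 1))
  expect_false(anyNA(gt$geno))

  cfg_m <- small_config(seed = 3, missing_rate = 0.2)
  gtm <- simulate_genotypes(cfg_m, ped)
  expect_true(anyNA(gtm$geno))
  expect_false(anyNA(attr(gtm$geno, "complete")))

  # maximal correlation, one founder: haplotypes constant along a chromosome
  cfg1 <- sim_config(n_founders = 1, n_generations = 0, n_chromosomes = 2,
                     n_markers_per_chromosome = 30, ld_decay = 0, seed = 5)
  ped1 <- simulate_pedigree(cfg1)
  gt1 <- simulate_genotypes(cfg1, ped1)
  for (c_ in 1:2) {
    gchr <- gt1$geno[1, gt1$map$chromosome == c_]
    expect_equal(length(unique(gchr)), 1L)
  }
})

test_that("adjacent-marker correlation decreases toward ld independence", {
  adj_cor <- function(ld) {
    cfg <- sim_config(n_founders = 1200, n_generations = 0, n_chromosomes = 1,
                      n_markers_per_chromosome = 40, ld_decay = ld,
                      maf_spectrum = c(0.2, 0.5), seed = 8)
    gt <- simulate_genotypes(cfg, simulate_pedigree(cfg))
    g <- gt$geno
    mean(vapply(seq_len(ncol(g) - 1),
                function(j) abs(cor(g[, j], g[, j + 1])), numeric(1)))
  }
  r <- vapply(c(0.05, 0.4, 1), adj_cor, numeric(1))
  expect_gt(r[1], r[2])
  expect_gt(r[2], r[3])
  expect_lt(r[3], 0.15)  # independence limit
})

test_that("founder allele frequencies follow the configured spectrum", {
  cfg <- sim_config(n_founders = 1500, n_generations = 0, n_chromosomes = 1,
                    n_markers_per_chromosome = 300, ld_decay = 1,
                    maf_spectrum = c(0.1, 0.5), seed = 12)
  gt <- simulate_genotypes(cfg, simulate_pedigree(cfg))
  freq <- colMeans(gt$geno) / 2
  expect_true(all(freq > 0.05 & freq < 0.62))
  expect_equal(mean(freq), 0.3, tolerance = 0.05)
})

test_that("phenotypes degenerate correctly and scale with weights", {
  cfg <- small_config(seed = 4, sigma2_u = 0, sigma2_e = 0, n_qtl = 0,
                      qtl_variance_fraction = 0, mu = 2.5)
  ped <- simulate_pedigree(cfg)
  A <- build_relationship_matrix(ped)
  gt <- simulate_genotypes(cfg, ped)
  ph <- simulate_phenotypes(cfg, gt$geno, A, gt$map)
  expect_true(all(ph$phenotypes$y_c == 2.5))

  # residual variance scales as sigma2_e / w: compare w = 1 vs w = 4 cohorts
  res_var <- function(wfix, seed) {
    cfg <- sim_config(n_founders = 10000, n_generations = 0, n_chromosomes = 1,
                      n_markers_per_chromosome = 2, n_qtl = 0,
                      qtl_variance_fraction = 0, sigma2_u = 0, sigma2_e = 1,
                      weight_range = c(wfix, wfix), seed = seed)
    ped <- simulate_pedigree(cfg)
    gt <- simulate_genotypes(cfg, ped)
    ph <- simulate_phenotypes(cfg, gt$geno, diag(nrow(ped)), gt$map)
    var(ph$phenotypes$y_c)
  }
  expect_equal(res_var(1, 31) / res_var(4, 32), 4, tolerance = 0.15)
})

test_that("polygenic values have covariance A * sigma2_u", {
  cfg <- small_config(seed = 6, n_founders = 6, n_generations = 1,
                      n_markers_per_chromosome = 4, n_qtl = 0,
                      qtl_variance_fraction = 0, sigma2_u = 2)
  ped <- simulate_pedigree(cfg)
  A <- build_relationship_matrix(ped)
  gt <- simulate_genotypes(cfg, ped)
  U <- sapply(1:400, function(k) {
    cfg$seed <- k
    simulate_phenotypes(cfg, gt$geno, A, gt$map)$truth$true_u
  })
  emp <- apply(U, 1, var)
  expect_equal(emp, 2 * diag(A), tolerance = 0.25, ignore_attr = TRUE)
})

test_that("planted QTL explain the configured fraction of additive variance", {
  cfg <- small_config(seed = 7, n_qtl = 2, qtl_variance_fraction = 0.5,
                      sigma2_u = 0.4)
  d <- simulate_dataset(cfg)
  X <- attr(d$geno, "complete")
  gv <- X[, d$truth$qtl_marker_indices, drop = FALSE] %*% d$truth$qtl_effects
  v_m <- mean((gv - mean(gv))^2)
  # target: v_m = sigma2_u * f / (1 - f), so v_m / (v_m + sigma2_u) = f
  expect_equal(v_m / (v_m + 0.4), 0.5, tolerance = 1e-10)
  expect_equal(nrow(d$truth$true_region_spans), 2)
  expect_true(all(d$truth$true_region_spans$chromosome %in% cfg$qtl_chromosomes))
})
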
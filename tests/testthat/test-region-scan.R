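make_map <- function(pos, chrom = rep(1L, length(pos))) {
  data.frame(marker_id = sprintf("m%03d", seq_along(pos)), chromosome = chrom,
             position_bp = pos, allele_1 = "A", allele_2 = "B",
             stringsAsFactors = FALSE)
}

test_that("windows are anchored at every marker and clip membership", {
  map <- make_map(c(1000000, 1500000))
  win <- build_windows(map, 1e6)
  expect_equal(nrow(win), 2)                       # one window per marker
  expect_equal(win$first_marker[1], 1)
  expect_equal(win$last_marker[1], 2)              # both markers inside [1.0, 2.0) Mb
  expect_equal(win$n_markers[2], 1)

  single <- build_windows(make_map(5e6), 2.5e6)
  expect_equal(nrow(single), 1)
  expect_equal(single$n_markers, 1)

  # window count equals marker count per chromosome
  map2 <- make_map(c(1e6, 2e6, 3e6, 1e6, 9e6), c(1L, 1L, 1L, 2L, 2L))
  expect_equal(nrow(build_windows(map2, 1e6)), 5)

  # membership is [start, end): a marker exactly at start + L is excluded
  map3 <- make_map(c(1e6, 2e6))
  expect_equal(build_windows(map3, 1e6)$last_marker[1], 1)

  expect_error(build_windows(make_map(c(2e6, 1e6)), 1e6), "sorted")
})

test_that("PP_int implements the at-least-one-large-effect definition", {
  map <- make_map(c(1e6, 1.5e6))
  win <- build_windows(map, 1e6)
  delta <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  win <- compute_pp_int(win, delta)
  expect_equal(win$pp_int[1], 0.75)   # 3 of 4 cycles have a large effect inside

  win0 <- compute_pp_int(build_windows(map, 1e6), matrix(0L, 5, 2))
  expect_equal(win0$pp_int, c(0, 0))

  # single-marker window equals that marker's inclusion frequency
  expect_equal(win$pp_int[2], mean(delta[, 2]))
})

test_that("vectorized PP_int equals the brute-force double loop", {
  set.seed(301)
  m <- 50
  map <- make_map(sort(sample.int(2e7, m)))
  delta <- matrix(rbinom(200 * m, 1, 0.08), 200, m)
  storage.mode(delta) <- "integer"
  for (L in c(5e5, 2e6, 7e6)) {
    win <- compute_pp_int(build_windows(map, L), delta)
    expect_identical(win$pp_int, pp_int_bruteforce(win, delta))
  }
})

test_that("nested windows never lose PP_int when enlarged", {
  set.seed(302)
  m <- 60
  map <- make_map(sort(sample.int(3e7, m)))
  delta <- matrix(rbinom(150 * m, 1, 0.05), 150, m)
  storage.mode(delta) <- "integer"
  w_small <- compute_pp_int(build_windows(map, 1e6), delta)
  w_big <- compute_pp_int(build_windows(map, 4e6), delta)
  # same anchor, longer window: superset membership
  expect_true(all(w_big$pp_int >= w_small$pp_int))
})

test_that("candidate peaks group overlapping hot windows", {
  win <- data.frame(chromosome = 1L,
                    start_bp = c(1e6, 1.4e6, 1.8e6, 2.2e6),
                    end_bp = c(2e6, 2.4e6, 2.8e6, 3.2e6),
                    first_marker = 1:4, last_marker = 1:4, n_markers = 1L,
                    pp_int = c(0.5, 0.85, 0.9, 0.5))
  pk <- find_candidate_peaks(win, 0.8)
  expect_length(pk, 1)
  expect_equal(nrow(pk[[1]]), 2)

  # two hot windows with a cold gap and no bp overlap: two peaks
  win2 <- win
  win2$pp_int <- c(0.9, 0.1, 0.1, 0.95)
  expect_length(find_candidate_peaks(win2, 0.8), 2)

  # threshold is strict: pp_int exactly 0.8 is not significant
  win3 <- win
  win3$pp_int <- c(0.8, 0.8, 0.8, 0.8)
  expect_length(find_candidate_peaks(win3, 0.8), 0)
})

test_that("region selection takes the highest PP_int with earliest-start ties", {
  pk1 <- data.frame(chromosome = 1L, start_bp = c(1, 2, 3) * 1e6,
                    end_bp = c(2, 3, 4) * 1e6, first_marker = 1:3,
                    last_marker = 1:3, n_markers = 1L,
                    pp_int = c(0.85, 0.92, 0.83))
  sel <- select_regions(structure(list(pk1), class = "qw_peaks"))
  expect_equal(sel$start_bp, 2e6)

  pk2 <- pk1[1:2, ]; pk2$pp_int <- c(0.9, 0.9)
  sel2 <- select_regions(structure(list(pk2), class = "qw_peaks"))
  expect_equal(sel2$start_bp, 1e6)

  sel3 <- select_regions(structure(list(pk1[2, ]), class = "qw_peaks"))
  expect_equal(sel3$pp_int, 0.92)

  expect_equal(nrow(select_regions(structure(list(), class = "qw_peaks"))), 0)
})

test_that("region variance matches hand calculations", {
  X <- cbind(c(0, 1, 2, 1), c(1, 1, 0, 0))
  # one cycle, one-marker region with g = 1: population variance of [0,1,2,1]
  fit <- fake_fit(g = matrix(c(1, 0), 1, 2), delta = matrix(0L, 1, 2),
                  u = matrix(0, 1, 4))
  rv <- region_variance(list(first_marker = 1, last_marker = 1), X, fit)
  expect_equal(rv$mean, 0.5)

  # zero effects across cycles: mean 0, sd 0 (total variance zero -> skipped)
  fit0 <- fake_fit(g = matrix(0, 3, 2), delta = matrix(0L, 3, 2),
                   u = matrix(0, 3, 4))
  rv0 <- suppressWarnings(region_variance(list(first_marker = 1, last_marker = 2),
                                          X, fit0))
  expect_equal(rv0$mean, 0)
  expect_equal(rv0$sd, 0)
  expect_equal(rv0$n_skipped, 3)

  # whole genome with u = 0: proportion exactly 1 every cycle
  set.seed(303)
  fitg <- fake_fit(g = matrix(rnorm(10), 5, 2), delta = matrix(0L, 5, 2),
                   u = matrix(0, 5, 4))
  rvg <- region_variance(list(first_marker = 1, last_marker = 2), X, fitg)
  expect_equal(rvg$proportion, 1)
  # marker-only denominator agrees when u is zero
  rvm <- region_variance(list(first_marker = 1, last_marker = 2), X, fitg,
                         denominator = "markers")
  expect_equal(rvm$proportion, 1)
})

test_that("the full region scan finds a planted QTL and reports its variance", {
  set.seed(304)
  cfg <- small_config(seed = 20, n_founders = 60, n_generations = 2,
                      n_markers_per_chromosome = 80,
                      qtl_variance_fraction = 0.7)
  d <- simulate_dataset(cfg)
  bm <- bayes_mixture(d$phenotypes$y_c, impute_missing_naive(d$geno),
                      pedigree = d$pedigree, weights = d$phenotypes$weight,
                      map = d$map, chain = gibbs_config(2600, 600, 2, seed = 21))
  rs <- qtl_regions(bm, window_bp = c(1e6, 2.5e6))
  expect_gt(nrow(rs$regions), 0)
  qtl_pos <- d$truth$true_region_spans
  hit <- any(rs$regions$chromosome == qtl_pos$chromosome[1] &
               rs$regions$start_bp <= qtl_pos$start_bp[1] &
               rs$regions$end_bp > qtl_pos$start_bp[1])
  expect_true(hit)
  expect_true(all(rs$regions$pp_int > 0.8))
  expect_true(all(rs$regions$variance_proportion >= 0 &
                    rs$regions$variance_proportion <= 1))
})
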
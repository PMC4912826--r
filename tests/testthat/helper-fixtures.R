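# Shared fixture builders for the test suite.

# Small config: 3-generation pedigree (~120 individuals), 2 chromosomes.
small_config <- function(seed = 1, ...) {
  args <- list(n_founders = 40, n_generations = 2, offspring_per_mating = 2,
               n_chromosomes = 2, chromosome_length_bp = 5e7,
               n_markers_per_chromosome = 60, ld_decay = 0.2,
               n_qtl = 1, qtl_variance_fraction = 0.6, qtl_chromosomes = 1,
               sigma2_u = 0.3, sigma2_e = 1, seed = seed)
  do.call(sim_config, modifyList(args, list(...)))
}

# Founders-only pedigree of n unrelated individuals.
founder_pedigree <- function(n) data.frame(id = seq_len(n), sire = 0L, dam = 0L)

# Minimal bayes_mixture-shaped object for summary/region functions.
fake_fit <- function(g, delta, u = NULL, mu = NULL, obs_index = NULL) {
  T_ <- nrow(g)
  n <- if (is.null(u)) 1L else ncol(u)
  structure(list(samples = list(g = g, delta = delta,
                                u = u %||% matrix(0, T_, n),
                                mu = mu %||% rep(0, T_),
                                sigma2_g0 = rep(1e-4, T_),
                                pi0 = rep(0.99, T_),
                                sigma2_u = rep(0.1, T_),
                                sigma2_e = rep(1, T_), n_saved = T_,
                                max_residual_drift = 0),
                 n = n, m = ncol(g), prior = mixture_prior(),
                 chain = gibbs_config(100, 10, 1), map = NULL,
                 genotypes = NULL, obs_index = obs_index %||% seq_len(n),
                 prior_only = FALSE),
            class = "bayes_mixture")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force PP_int: explicit double loop over windows and cycles.
pp_int_bruteforce <- function(windows, delta) {
  vapply(seq_len(nrow(windows)), function(k) {
    jj <- seq(windows$first_marker[k], windows$last_marker[k])
    hits <- 0L
    for (t_ in seq_len(nrow(delta)))
      if (any(delta[t_, jj] == 1L)) hits <- hits + 1L
    hits / nrow(delta)
  }, numeric(1))
}
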
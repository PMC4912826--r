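#' Two-component mixture prior for SNP effects
#'
#' SNP effects are a priori N(0, sigma2_g0) with probability pi0 (small
#' effects) and N(0, variance_ratio * sigma2_g0) with probability 1 - pi0
#' (large effects); pi0 carries a Beta(pi_a, pi_b) prior.  The defaults fix
#' the variance ratio at 100 and the Beta prior at Beta(100, 1), giving a
#' prior mean of about 0.99 for the small-effect probability.
#'
#' @param variance_ratio ratio sigma2_g1 / sigma2_g0 (> 1).
#' @param pi_a,pi_b Beta prior parameters for pi0.
#' @return Object of class \code{mixture_prior}.
#' @export
mixture_prior <- function(variance_ratio = 100, pi_a = 100, pi_b = 1) {
  stopifnot(variance_ratio > 1, pi_a > 0, pi_b > 0)
  structure(list(variance_ratio = variance_ratio, pi_a = pi_a, pi_b = pi_b),
            class = "mixture_prior")
}

#' Gibbs chain settings
#'
#' Defaults follow the standard long-chain protocol: 52,000 cycles, the first
#' 20,000 discarded as burn-in, every 20th of the remaining 32,000 saved,
#' leaving 1,600 posterior samples.
#'
#' @param n_cycles total Gibbs cycles.
#' @param burn_in cycles discarded before saving.
#' @param thin save every \code{thin}-th post-burn-in cycle.
#' @param seed integer RNG seed (NULL = continue from the session RNG).
#' @param sigma2_g0_max upper support bound keeping the flat-prior conditional
#'   of sigma2_g0 proper (NULL = 100 * var(y), set at run time).
#' @param check_every cycles between full residual-consistency refreshes.
#' @return Object of class \code{gibbs_config}.
#' @export
gibbs_config <- function(n_cycles = 52000, burn_in = 20000, thin = 20,
                         seed = NULL, sigma2_g0_max = NULL,
                         check_every = 500) {
  stopifnot(n_cycles >= 1, burn_in >= 0, burn_in < n_cycles, thin >= 1)
  structure(list(n_cycles = as.integer(n_cycles),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = seed, sigma2_g0_max = sigma2_g0_max,
                 check_every = as.integer(check_every)),
            class = "gibbs_config")
}

#' Number of posterior samples a chain configuration saves
#'
#' @param config a \code{\link{gibbs_config}}.
#' @return \code{floor((n_cycles - burn_in) / thin)}.
#' @export
n_saved_cycles <- function(config) {
  (config$n_cycles - config$burn_in) %/% config$thin
}

#' Bayesian two-component mixture GWAS by Gibbs sampling
#'
#' Fits y = 1*mu + sum_j x_j g_j + Z u + e with all SNP effects in the model
#' simultaneously.  Each effect follows the two-normal mixture of
#' \code{\link{mixture_prior}}; the per-marker indicator delta_j (1 = large
#' effect) is drawn with g_j integrated out, the polygenic vector u is updated
#' element-wise through the sparse pedigree-based inverse of A, and flat
#' priors are used for mu, sigma2_g0 (bounded support), sigma2_u and sigma2_e.
#' Residuals are heteroscedastic with per-record weights
#' (var(e_i) = sigma2_e / w_i), matching the weighted linear mixed model.
#'
#' @param y corrected phenotypes, one record per genotyped individual.
#' @param genotypes n x m genotype matrix coded 0/1/2, no missing values.
#' @param pedigree pedigree data frame covering (at least) the phenotyped
#'   individuals; alternatively pass a precomputed sparse A-inverse via
#'   \code{A_inverse}.
#' @param weights positive reliability weights (default 1).
#' @param prior a \code{\link{mixture_prior}}.
#' @param chain a \code{\link{gibbs_config}}.
#' @param A_inverse optional sparse inverse relationship matrix
#'   (\code{dgCMatrix}); overrides \code{pedigree}.
#' @param obs_index 1-based pedigree positions of the phenotype records
#'   (default: records are the first \code{length(y)} pedigree entries when a
#'   pedigree is given, or all of them when ids match).
#' @param map optional marker map stored in the fit for region scanning.
#' @param prior_only when TRUE the likelihood is switched off and the sampler
#'   draws delta, g and pi0 from the prior (used for sampler validation).
#' @return Object of class \code{bayes_mixture} holding thinned posterior
#'   samples (\code{g}, \code{delta}, \code{u}, \code{mu}, \code{sigma2_g0},
#'   \code{pi0}, \code{sigma2_u}, \code{sigma2_e}), dimensions, settings and
#'   the genotype matrix (for region-variance summaries).
#' @export
bayes_mixture <- function(y, genotypes, pedigree = NULL,
                          weights = rep(1, length(y)),
                          prior = mixture_prior(), chain = gibbs_config(),
                          A_inverse = NULL, obs_index = NULL, map = NULL,
                          prior_only = FALSE) {
  n <- length(y)
  X <- genotypes
  if (anyNA(X)) stop("genotypes contain missing values: run imputation first")
  stopifnot(nrow(X) == n, all(weights > 0), length(weights) == n)
  if (is.null(A_inverse)) {
    if (is.null(pedigree))
      stop("either a pedigree or a sparse A-inverse is required")
    A_inverse <- relationship_inverse(pedigree)
    if (is.null(obs_index)) {
      ids <- rownames(X)
      obs_index <- if (!is.null(ids) && all(ids %in% as.character(pedigree$id)))
        match(ids, as.character(pedigree$id)) else seq_len(n)
    }
  }
  if (is.null(obs_index)) obs_index <- seq_len(n)
  stopifnot(length(obs_index) == n, !anyNA(obs_index))
  Ainv <- methods::as(methods::as(A_inverse, "CsparseMatrix"), "generalMatrix")
  vy <- var(y)
  s2max <- chain$sigma2_g0_max %||% (100 * max(vy, 1e-8))
  storage.mode(X) <- "double"
  # centre genotype columns so the intercept and marker effects are not
  # confounded (a zero-variance marker then has a flat likelihood in g_j);
  # effects, indicators and genetic variances are invariant to centring
  Xc <- X - rep(colMeans(X), each = n)
  if (!is.null(chain$seed)) set.seed(chain$seed)
  sam <- gibbs_mixture_cpp(as.numeric(y), as.numeric(weights), Xc,
                           as.integer(obs_index) - 1L,
                           Ainv@p, Ainv@i, Ainv@x,
                           chain$n_cycles, chain$burn_in, chain$thin,
                           prior$pi_a, prior$pi_b, prior$variance_ratio,
                           s2max, chain$check_every, prior_only,
                           max(vy, 1e-8) / max(ncol(X), 1),
                           max(vy, 1e-8) / 4, max(vy, 1e-8) / 2)
  colnames(sam$g) <- colnames(X)
  colnames(sam$delta) <- colnames(X)
  structure(list(samples = sam, n = n, m = ncol(X), prior = prior,
                 chain = chain, map = map, genotypes = X,
                 obs_index = obs_index, prior_only = prior_only),
            class = "bayes_mixture")
}

#' Posterior summaries of a mixture-model fit
#'
#' @param fit a \code{\link{bayes_mixture}} object.
#' @return \code{list(markers, chain)}: per-marker posterior mean/SD of the
#'   effect and the posterior inclusion frequency mean(delta_j), plus
#'   mean/SD chain summaries for mu, sigma2_g0, pi0, sigma2_u and sigma2_e.
#' @export
posterior_summaries <- function(fit) {
  stopifnot(inherits(fit, "bayes_mixture"))
  s <- fit$samples
  if (nrow(s$g) < 1) stop("no saved cycles to summarise")
  markers <- data.frame(marker_id = colnames(s$g) %||% seq_len(ncol(s$g)),
                        effect_mean = colMeans(s$g),
                        effect_sd = apply(s$g, 2, sd),
                        inclusion_frequency = colMeans(s$delta),
                        stringsAsFactors = FALSE)
  scalars <- c("mu", "sigma2_g0", "pi0", "sigma2_u", "sigma2_e")
  chain <- data.frame(parameter = scalars,
                      mean = vapply(scalars, function(p) mean(s[[p]]), 0),
                      sd = vapply(scalars, function(p) sd(s[[p]]), 0))
  list(markers = markers, chain = chain)
}

#' @export
print.bayes_mixture <- function(x, ...) {
  cat(sprintf("Bayesian mixture-model GWAS fit: %d individuals, %d markers\n",
              x$n, x$m))
  cat(sprintf("  chain: %d cycles, %d burn-in, thin %d -> %d saved samples\n",
              x$chain$n_cycles, x$chain$burn_in, x$chain$thin,
              x$samples$n_saved))
  cat(sprintf("  prior: variance ratio %g, pi0 ~ Beta(%g, %g)\n",
              x$prior$variance_ratio, x$prior$pi_a, x$prior$pi_b))
  if (!x$prior_only) {
    s <- x$samples
    cat(sprintf("  posterior means: pi0 = %.4f, sigma2_g0 = %.3g, sigma2_u = %.3g, sigma2_e = %.3g\n",
                mean(s$pi0), mean(s$sigma2_g0), mean(s$sigma2_u),
                mean(s$sigma2_e)))
    cat(sprintf("  max residual drift between refreshes: %.2e\n",
                s$max_residual_drift))
  }
  invisible(x)
}

#' @export
summary.bayes_mixture <- function(object, n_top = 10, ...) {
  print(object)
  ps <- posterior_summaries(object)
  ord <- order(-ps$markers$inclusion_frequency)
  cat("\nMarkers with highest posterior inclusion frequency:\n")
  print(head(ps$markers[ord, ], n_top), row.names = FALSE)
  invisible(ps)
}

#' @export
coef.bayes_mixture <- function(object, ...) {
  setNames(colMeans(object$samples$g), colnames(object$samples$g))
}

#' Posterior inclusion-frequency track plot
#'
#' @param x a \code{bayes_mixture} fit (needs its marker map).
#' @param ... passed to \code{plot}.
#' @export
plot.bayes_mixture <- function(x, ...) {
  pip <- colMeans(x$samples$delta)
  if (is.null(x$map)) {
    graphics::plot(pip, pch = 20, cex = 0.5, xlab = "marker index",
                   ylab = "posterior inclusion frequency", ...)
  } else {
    off <- c(0, cumsum(tapply(x$map$position_bp, x$map$chromosome, max)))
    xs <- x$map$position_bp +
      off[match(x$map$chromosome, sort(unique(x$map$chromosome)))]
    graphics::plot(xs, pip, pch = 20, cex = 0.5,
                   col = (x$map$chromosome %% 2) + 1,
                   xlab = "genome position",
                   ylab = "posterior inclusion frequency", ...)
  }
  invisible(x)
}
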
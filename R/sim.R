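#' Simulation settings for a pig-like pedigreed GWAS dataset
#'
#' Bundles every knob of the synthetic-data generator: a discrete-generation
#' pedigree, LD-structured 0/1/2 genotypes over several autosomes, planted
#' large-effect QTL, a pedigree polygenic term and heteroscedastic residuals
#' controlled by per-record reliability weights.  The defaults describe the
#' standard study conditions used throughout the package's tests: 250 founders
#' plus three generations of 250 (1,000 individuals), 4 chromosomes of 100 Mb
#' carrying 500 markers each (2,000 markers), and four large-effect QTL placed
#' on chromosomes 1 and 2 so that two chromosomes stay QTL-free.
#'
#' @param n_founders number of unrelated founder animals (generation 0).
#' @param n_generations number of discrete offspring generations.
#' @param offspring_per_mating litter size per mating pair.
#' @param n_chromosomes number of autosomes.
#' @param chromosome_length_bp physical length of each autosome in base pairs.
#' @param n_markers_per_chromosome markers per autosome.
#' @param ld_decay probability, per adjacent-marker transition, that a founder
#'   haplotype draws a fresh allele instead of copying its neighbour; 0 gives
#'   maximal LD (whole-chromosome haplotype blocks), 1 gives independent loci.
#' @param maf_spectrum length-2 interval; founder allele-2 frequencies are
#'   drawn uniformly from it.
#' @param n_qtl number of planted large-effect QTL.
#' @param qtl_variance_fraction fraction of the additive genetic variance
#'   (planted marker variance + polygenic \code{sigma2_u}) carried by the
#'   planted QTL, in [0, 1).
#' @param qtl_chromosomes chromosomes eligible to carry QTL (NULL = all).
#' @param qtl_min_gap_bp minimum distance between two QTL on one chromosome.
#' @param sigma2_u polygenic variance (covariance \code{A * sigma2_u}).
#' @param sigma2_e residual variance at weight 1; record i gets variance
#'   \code{sigma2_e / w_i}.
#' @param weight_range positive interval from which reliability weights are
#'   drawn uniformly.
#' @param missing_rate probability that a genotype call is missing.
#' @param mu overall trait mean.
#' @param seed integer seed; identical configs give bit-identical datasets.
#' @return An object of class \code{sim_config} (a validated list).
#' @export
sim_config <- function(n_founders = 250, n_generations = 3,
                       offspring_per_mating = 2, n_chromosomes = 4,
                       chromosome_length_bp = 1e8,
                       n_markers_per_chromosome = 500, ld_decay = 0.1,
                       maf_spectrum = c(0.05, 0.5), n_qtl = 4,
                       qtl_variance_fraction = 0.77,
                       qtl_chromosomes = c(1, 2), qtl_min_gap_bp = 2e7,
                       sigma2_u = 0.3, sigma2_e = 1,
                       weight_range = c(0.5, 4), missing_rate = 0,
                       mu = 0, seed = 1) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              offspring_per_mating = as.integer(offspring_per_mating),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length_bp = as.numeric(chromosome_length_bp),
              n_markers_per_chromosome = as.integer(n_markers_per_chromosome),
              ld_decay = ld_decay, maf_spectrum = maf_spectrum,
              n_qtl = as.integer(n_qtl),
              qtl_variance_fraction = qtl_variance_fraction,
              qtl_chromosomes = qtl_chromosomes,
              qtl_min_gap_bp = qtl_min_gap_bp,
              sigma2_u = sigma2_u, sigma2_e = sigma2_e,
              weight_range = weight_range, missing_rate = missing_rate,
              mu = mu, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_cfg <- function(ok, msg) if (!ok) stop("invalid sim_config: ", msg,
                                                   call. = FALSE)
  stopifnot_cfg(cfg$n_founders >= 1, "n_founders must be >= 1")
  stopifnot_cfg(cfg$n_generations >= 0, "n_generations must be >= 0")
  stopifnot_cfg(cfg$offspring_per_mating >= 1, "offspring_per_mating must be >= 1")
  stopifnot_cfg(cfg$n_chromosomes >= 1, "n_chromosomes must be >= 1")
  stopifnot_cfg(cfg$chromosome_length_bp >= 1, "chromosome_length_bp must be >= 1")
  stopifnot_cfg(cfg$n_markers_per_chromosome >= 1,
                "n_markers_per_chromosome must be >= 1")
  stopifnot_cfg(cfg$ld_decay >= 0 && cfg$ld_decay <= 1, "ld_decay must be in [0,1]")
  stopifnot_cfg(length(cfg$maf_spectrum) == 2 && all(cfg$maf_spectrum > 0) &&
                  all(cfg$maf_spectrum < 1) && diff(cfg$maf_spectrum) >= 0,
                "maf_spectrum must be an increasing interval inside (0,1)")
  stopifnot_cfg(cfg$n_qtl >= 0, "n_qtl must be >= 0")
  stopifnot_cfg(cfg$qtl_variance_fraction >= 0 && cfg$qtl_variance_fraction < 1,
                "qtl_variance_fraction must be in [0,1)")
  stopifnot_cfg(cfg$sigma2_u >= 0 && cfg$sigma2_e >= 0, "variances must be >= 0")
  stopifnot_cfg(length(cfg$weight_range) == 2 && all(cfg$weight_range > 0) &&
                  diff(cfg$weight_range) >= 0,
                "weight_range bounds must be positive and increasing")
  stopifnot_cfg(cfg$missing_rate >= 0 && cfg$missing_rate <= 1,
                "missing_rate must be in [0,1]")
  invisible(cfg)
}

#' Simulate a discrete-generation pedigree
#'
#' Founders (generation 0) have unknown parents.  Each later generation is
#' produced by randomly pairing the previous generation into disjoint mating
#' couples, every couple contributing \code{offspring_per_mating} offspring.
#' Individuals are numbered so parents always precede offspring.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A data frame of class \code{qw_pedigree} with columns
#'   \code{id}, \code{sire}, \code{dam} (0 = unknown) and \code{generation}.
#' @export
simulate_pedigree <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed + 101L, {
    id <- seq_len(config$n_founders)
    sire <- dam <- rep(0L, config$n_founders)
    gen <- rep(0L, config$n_founders)
    prev <- id
    for (gidx in seq_len(config$n_generations)) {
      if (length(prev) < 2L)
        stop("generation ", gidx - 1L, " has fewer than 2 individuals to mate")
      perm <- sample(prev)
      n_pairs <- length(perm) %/% 2L
      sires <- perm[seq_len(n_pairs) * 2L - 1L]
      dams <- perm[seq_len(n_pairs) * 2L]
      kid_s <- rep(sires, each = config$offspring_per_mating)
      kid_d <- rep(dams, each = config$offspring_per_mating)
      kids <- max(id) + seq_along(kid_s)
      id <- c(id, kids)
      sire <- c(sire, kid_s)
      dam <- c(dam, kid_d)
      gen <- c(gen, rep(gidx, length(kids)))
      prev <- kids
    }
    structure(data.frame(id = as.integer(id), sire = as.integer(sire),
                         dam = as.integer(dam), generation = as.integer(gen)),
              class = c("qw_pedigree", "data.frame"))
  })
}

check_pedigree <- function(pedigree) {
  stopifnot(all(c("id", "sire", "dam") %in% names(pedigree)))
  n <- nrow(pedigree)
  pos <- match(pedigree$sire, pedigree$id)
  pos[pedigree$sire == 0L] <- 0L
  dpos <- match(pedigree$dam, pedigree$id)
  dpos[pedigree$dam == 0L] <- 0L
  if (anyNA(pos) || anyNA(dpos))
    stop("pedigree references unknown parent ids")
  if (any(pos > seq_len(n)) || any(dpos > seq_len(n)))
    stop("pedigree is not ordered parents-before-offspring")
  list(sire = as.integer(pos), dam = as.integer(dpos))
}

#' Pedigree-based additive relationship matrix (tabular method)
#'
#' Builds the numerator relationship matrix A with the classic tabular
#' recursion: \code{a_ii = 1 + 0.5 a(sire_i, dam_i)} and
#' \code{a_ij = 0.5 (a(j, sire_i) + a(j, dam_i))}, unknown parents
#' contributing zero.
#'
#' @param pedigree a pedigree data frame ordered parents-before-offspring.
#' @return A symmetric positive semi-definite numeric matrix with one
#'   row/column per pedigree individual.
#' @export
build_relationship_matrix <- function(pedigree) {
  par <- check_pedigree(pedigree)
  A <- a_matrix_cpp(par$sire, par$dam)
  dimnames(A) <- list(pedigree$id, pedigree$id)
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules with the
#' inbreeding correction (Mendelian-sampling variances computed from the
#' tabular-method inbreeding coefficients), yielding the sparse matrix used by
#' the Gibbs sampler's element-wise polygenic updates.
#'
#' @param pedigree a pedigree data frame ordered parents-before-offspring.
#' @return A \code{\link[Matrix]{dgCMatrix}} equal to \code{solve(A)}.
#' @export
relationship_inverse <- function(pedigree) {
  par <- check_pedigree(pedigree)
  n <- nrow(pedigree)
  Fi <- diag(a_matrix_cpp(par$sire, par$dam)) - 1
  ii <- jj <- integer(9L * n)
  xx <- numeric(9L * n)
  k <- 0L
  add <- function(i, j, v) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- v
  }
  for (i in seq_len(n)) {
    s <- par$sire[i]; d <- par$dam[i]
    di <- if (s > 0L && d > 0L) 0.5 - 0.25 * (Fi[s] + Fi[d])
          else if (s > 0L) 0.75 - 0.25 * Fi[s]
          else if (d > 0L) 0.75 - 0.25 * Fi[d]
          else 1
    al <- 1 / di
    add(i, i, al)
    for (p in c(s, d)) if (p > 0L) {
      add(i, p, -al / 2); add(p, i, -al / 2)
      add(p, p, al / 4)
    }
    if (s > 0L && d > 0L && s != d) {
      add(s, d, al / 4); add(d, s, al / 4)
    }
  }
  ii <- ii[seq_len(k)]; jj <- jj[seq_len(k)]; xx <- xx[seq_len(k)]
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n), repr = "C")
}

#' Simulate LD-structured SNP genotypes on a pedigree
#'
#' Founder haplotypes follow a first-order Markov chain along each chromosome:
#' each allele copies its left neighbour with probability \code{1 - ld_decay}
#' and otherwise is a fresh Bernoulli draw at that marker's founder frequency
#' (drawn from \code{maf_spectrum}).  Offspring receive recombined parental
#' gametes with one uniformly positioned crossover per chromosome per meiosis.
#' Missing calls are inserted at \code{missing_rate}; per-marker mean GenCall
#' scores are drawn Beta(20, 2).
#'
#' @param config a \code{\link{sim_config}}.
#' @param pedigree pedigree the genotypes descend through.
#' @return \code{list(map, geno)}: \code{map} is a marker map data frame
#'   (marker_id, chromosome, position_bp, allele_1, allele_2); \code{geno} is
#'   an n x m integer matrix of allele-2 counts with NA for missing calls and
#'   attributes \code{mean_gencall} (per marker) and \code{complete} (the
#'   missingness-free matrix, used as simulation ground truth).
#' @export
simulate_genotypes <- function(config, pedigree) {
  validate_sim_config(config)
  par <- check_pedigree(pedigree)
  n <- nrow(pedigree)
  mc <- config$n_markers_per_chromosome
  m <- config$n_chromosomes * mc
  with_seed(config$seed + 202L, {
    pos <- integer(0); chr <- integer(0)
    for (c_ in seq_len(config$n_chromosomes)) {
      p <- sort(sample.int(config$chromosome_length_bp, mc))
      pos <- c(pos, p)
      chr <- c(chr, rep(c_, mc))
    }
    freq <- runif(m, config$maf_spectrum[1], config$maf_spectrum[2])
    H1 <- matrix(0L, n, m)
    H2 <- matrix(0L, n, m)
    founders <- which(pedigree$sire == 0L & pedigree$dam == 0L)
    nf <- length(founders)
    for (c_ in seq_len(config$n_chromosomes)) {
      cols <- (c_ - 1L) * mc + seq_len(mc)
      for (H in c("H1", "H2")) {
        hap <- matrix(0L, nf, mc)
        hap[, 1] <- rbinom(nf, 1L, freq[cols[1]])
        for (k in seq_len(mc)[-1]) {
          fresh <- runif(nf) < config$ld_decay
          hap[, k] <- ifelse(fresh, rbinom(nf, 1L, freq[cols[k]]), hap[, k - 1])
        }
        if (H == "H1") H1[founders, cols] <- hap else H2[founders, cols] <- hap
      }
    }
    nonf <- which(par$sire > 0L | par$dam > 0L)
    gamete <- function(p_idx, cols, cpos) {
      xo <- runif(1) * config$chromosome_length_bp
      first <- runif(1) < 0.5
      left <- cpos <= xo
      if (first) ifelse(left, H1[p_idx, cols], H2[p_idx, cols])
      else ifelse(left, H2[p_idx, cols], H1[p_idx, cols])
    }
    for (i in nonf) {
      for (c_ in seq_len(config$n_chromosomes)) {
        cols <- (c_ - 1L) * mc + seq_len(mc)
        cpos <- pos[cols]
        H1[i, cols] <- gamete(par$sire[i], cols, cpos)
        H2[i, cols] <- gamete(par$dam[i], cols, cpos)
      }
    }
    X <- H1 + H2
    storage.mode(X) <- "integer"
    complete <- X
    if (config$missing_rate > 0) {
      miss <- matrix(runif(n * m) < config$missing_rate, n, m)
      X[miss] <- NA_integer_
    }
    gencall <- rbeta(m, 20, 2)
    map <- data.frame(marker_id = sprintf("chr%d_m%04d", chr,
                                          sequence(rep(mc, config$n_chromosomes))),
                      chromosome = chr, position_bp = pos,
                      allele_1 = "A", allele_2 = "B",
                      stringsAsFactors = FALSE)
    rownames(X) <- pedigree$id
    colnames(X) <- map$marker_id
    attr(X, "mean_gencall") <- gencall
    attr(X, "complete") <- complete
    list(map = map, geno = X)
  })
}

#' Simulate weighted corrected phenotypes with planted QTL
#'
#' Chooses \code{n_qtl} markers as large-effect QTL (restricted to
#' \code{qtl_chromosomes}, pairwise at least \code{qtl_min_gap_bp} apart,
#' in-sample minor allele frequency at least 0.1), assigns alternating-sign
#' effects rescaled so the planted QTL jointly explain exactly
#' \code{qtl_variance_fraction} of the additive genetic variance (planted
#' marker variance plus \code{sigma2_u}) in-sample, draws polygenic values
#' \code{u ~ N(0, A sigma2_u)} and residuals \code{e_i ~ N(0, sigma2_e/w_i)}
#' with weights uniform on \code{weight_range}, and returns
#' \code{y_c = mu + X g + u + e} with full ground truth.
#'
#' @param config a \code{\link{sim_config}}.
#' @param genotypes genotype matrix from \code{\link{simulate_genotypes}} (its
#'   \code{complete} attribute is used when present, so missingness never
#'   contaminates the truth).
#' @param A additive relationship matrix for the same individuals.
#' @param map marker map (needed to honour QTL placement constraints).
#' @return \code{list(phenotypes, truth)}: a data frame (id, trait, y_c,
#'   weight) and a truth list (qtl_marker_indices, qtl_effects, true_u,
#'   true_region_spans, marker_effects).
#' @export
simulate_phenotypes <- function(config, genotypes, A, map = NULL) {
  validate_sim_config(config)
  X <- attr(genotypes, "complete") %||% genotypes
  if (anyNA(X)) stop("genotypes contain missing values and no complete copy")
  n <- nrow(X); m <- ncol(X)
  if (nrow(A) != n) stop("relationship matrix dimension does not match genotypes")
  with_seed(config$seed + 303L, {
    g <- numeric(m)
    qtl_idx <- integer(0)
    v_target <- if (config$qtl_variance_fraction > 0)
      config$sigma2_u * config$qtl_variance_fraction /
        (1 - config$qtl_variance_fraction) else 0
    if (config$n_qtl > 0L && v_target > 0) {
      frq <- colMeans(X) / 2
      elig <- which(pmin(frq, 1 - frq) >= 0.1)
      if (!is.null(map) && !is.null(config$qtl_chromosomes))
        elig <- elig[map$chromosome[elig] %in% config$qtl_chromosomes]
      if (length(elig) < config$n_qtl)
        stop("not enough eligible markers to place ", config$n_qtl, " QTL")
      pool <- sample(elig)
      for (cand in pool) {
        ok <- TRUE
        if (!is.null(map) && length(qtl_idx)) {
          same <- qtl_idx[map$chromosome[qtl_idx] == map$chromosome[cand]]
          if (length(same) &&
              any(abs(map$position_bp[same] - map$position_bp[cand]) <
                    config$qtl_min_gap_bp)) ok <- FALSE
        }
        if (ok) qtl_idx <- c(qtl_idx, cand)
        if (length(qtl_idx) == config$n_qtl) break
      }
      if (length(qtl_idx) < config$n_qtl)
        stop("could not place ", config$n_qtl,
             " QTL under the minimum-gap constraint")
      sdx <- apply(X[, qtl_idx, drop = FALSE], 2, sd)
      sdx[sdx == 0] <- 1
      base <- (-1)^(seq_along(qtl_idx) - 1) / sdx
      gv <- as.numeric(X[, qtl_idx, drop = FALSE] %*% base)
      vg <- pop_var(gv)
      if (vg <= 0) stop("planted QTL genotypes carry no variance")
      g[qtl_idx] <- base * sqrt(v_target / vg)
    }
    xb <- as.numeric(X %*% g)
    u <- numeric(n)
    if (config$sigma2_u > 0) {
      L <- tryCatch(chol(A), error = function(e)
        stop("relationship matrix is not positive definite: ",
             conditionMessage(e), call. = FALSE))
      u <- as.numeric(crossprod(L, rnorm(n))) * sqrt(config$sigma2_u)
    }
    w <- runif(n, config$weight_range[1], config$weight_range[2])
    e <- rnorm(n, 0, sqrt(config$sigma2_e / w))
    y <- config$mu + xb + u + e
    spans <- if (length(qtl_idx) && !is.null(map))
      data.frame(chromosome = map$chromosome[qtl_idx],
                 start_bp = map$position_bp[qtl_idx],
                 end_bp = map$position_bp[qtl_idx])
    else data.frame(chromosome = integer(0), start_bp = integer(0),
                    end_bp = integer(0))
    list(phenotypes = data.frame(id = rownames(X) %||% seq_len(n),
                                 trait = "trait", y_c = y, weight = w,
                                 stringsAsFactors = FALSE),
         truth = list(qtl_marker_indices = qtl_idx,
                      qtl_effects = g[qtl_idx],
                      true_u = u,
                      true_region_spans = spans,
                      marker_effects = g))
  })
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running \code{\link{simulate_pedigree}},
#' \code{\link{build_relationship_matrix}}, \code{\link{simulate_genotypes}}
#' and \code{\link{simulate_phenotypes}} in sequence.
#'
#' @param config a \code{\link{sim_config}}.
#' @return \code{list(config, pedigree, A, map, geno, phenotypes, truth)}.
#' @export
simulate_dataset <- function(config) {
  ped <- simulate_pedigree(config)
  A <- build_relationship_matrix(ped)
  gt <- simulate_genotypes(config, ped)
  ph <- simulate_phenotypes(config, gt$geno, A, gt$map)
  list(config = config, pedigree = ped, A = A, map = gt$map, geno = gt$geno,
       phenotypes = ph$phenotypes, truth = ph$truth)
}
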
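#' REML variance components for the weighted null polygenic model
#'
#' Fits y = 1*mu + u + e with u ~ N(0, A sigma2_u) and
#' e ~ N(0, D sigma2_e), D = diag(1/w_i), by exact restricted maximum
#' likelihood.  A single eigendecomposition of W^(1/2) A W^(1/2) reduces the
#' problem to a one-dimensional search over the variance ratio
#' gamma = sigma2_u / sigma2_e, profiled in closed form over mu and sigma2_e;
#' the ratio is optimised by Brent's method on a log grid and the boundary
#' gamma = 0 is checked explicitly (negative-variance estimates are clamped
#' to zero there).
#'
#' @param y numeric vector of corrected phenotypes.
#' @param weights positive reliability weights (residual variance
#'   \code{sigma2_e / w_i}).
#' @param A additive relationship matrix (positive semi-definite).
#' @return Object of class \code{qw_vc}: \code{sigma2_u}, \code{sigma2_e},
#'   \code{gamma}, REML log-likelihood, and the cached rotation (eigenvectors,
#'   eigenvalues, rotated intercept/phenotype) reused by the association scan.
#' @export
estimate_null_variance_components <- function(y, weights, A) {
  n <- length(y)
  stopifnot(length(weights) == n, nrow(A) == n, all(weights > 0))
  if (var(y) == 0)
    stop("phenotype is constant: variance components are undefined")
  sw <- sqrt(weights)
  K <- sw * t(sw * A)             # W^(1/2) A W^(1/2), symmetric
  eig <- eigen(K, symmetric = TRUE)
  lam <- pmax(eig$values, 0)
  yt <- crossprod(eig$vectors, sw * y)[, 1]
  xt <- crossprod(eig$vectors, sw)[, 1]

  reml_ll <- function(log_gamma) {
    g <- exp(log_gamma)
    v <- 1 + g * lam
    xvx <- sum(xt^2 / v)
    beta <- sum(xt * yt / v) / xvx
    rss <- sum((yt - xt * beta)^2 / v)
    s2e <- rss / (n - 1)
    -0.5 * ((n - 1) * (log(2 * pi * s2e) + 1) + sum(log(v)) + log(xvx))
  }
  opt <- optimize(reml_ll, interval = c(-25, 25), maximum = TRUE, tol = 1e-10)
  ll0 <- reml_ll(-Inf)  # gamma = 0 boundary
  # prefer the boundary when it fits essentially as well (flat or null
  # likelihoods, e.g. A = I where only sigma2_u + sigma2_e is identified)
  if (ll0 >= opt$objective - 1e-6) {
    gamma <- 0
    ll <- ll0
  } else {
    gamma <- exp(opt$maximum)
    ll <- opt$objective
  }
  v <- 1 + gamma * lam
  beta <- sum(xt * yt / v) / sum(xt^2 / v)
  s2e <- sum((yt - xt * beta)^2 / v) / (n - 1)
  structure(list(sigma2_u = gamma * s2e, sigma2_e = s2e, gamma = gamma,
                 loglik = ll, n = n,
                 rotation = list(vectors = eig$vectors, values = lam,
                                 sqrt_w = sw, yt = yt, xt = xt)),
            class = "qw_vc")
}

#' @export
print.qw_vc <- function(x, ...) {
  cat("REML variance components (weighted polygenic null model)\n")
  cat(sprintf("  sigma2_u = %.6g\n  sigma2_e = %.6g\n  gamma    = %.6g\n",
              x$sigma2_u, x$sigma2_e, x$gamma))
  cat(sprintf("  REML log-likelihood = %.4f  (n = %d)\n", x$loglik, x$n))
  invisible(x)
}

#' Single-SNP weighted mixed-model association scan
#'
#' Fits, for every marker, y = 1*mu + x g + u + e by generalised least
#' squares under V = A sigma2_u + D sigma2_e with the variance components
#' estimated once on the null model and held fixed across markers (two-stage
#' scan).  Effects are tested with a two-sided t-test on n - 2 degrees of
#' freedom, the per-marker residual variance being re-estimated from the
#' whitened residuals so that the scan reduces exactly to ordinary least
#' squares when sigma2_u = 0 and all weights are 1.  Monomorphic markers are
#' reported with NA effect and p = 1.
#'
#' @param y corrected phenotypes.
#' @param genotypes n x m genotype matrix, no missing values (impute first).
#' @param A additive relationship matrix.
#' @param weights positive reliability weights (default all 1).
#' @param map optional marker map carried into the results.
#' @param vc optional precomputed \code{qw_vc}; estimated when NULL.
#' @param alpha nominal genome-wide levels for Bonferroni flags.
#' @return Object of class \code{lmm_gwas} with a per-marker \code{results}
#'   data frame (effect, se, t, p, neg_log10_p, significance flags), the
#'   variance components, Bonferroni thresholds and the genomic inflation
#'   factor of the scan.
#' @export
lmm_gwas <- function(y, genotypes, A, weights = rep(1, length(y)), map = NULL,
                     vc = NULL, alpha = c(0.05, 0.01)) {
  n <- length(y)
  X <- genotypes
  if (anyNA(X)) stop("genotypes contain missing values: run imputation first")
  stopifnot(nrow(X) == n)
  m <- ncol(X)
  if (is.null(vc)) vc <- estimate_null_variance_components(y, weights, A)
  rot <- vc$rotation
  if (is.null(rot) || length(rot$yt) != n) {
    sw <- sqrt(weights)
    K <- sw * t(sw * A)
    eig <- eigen(K, symmetric = TRUE)
    rot <- list(vectors = eig$vectors, values = pmax(eig$values, 0),
                sqrt_w = sw, yt = crossprod(eig$vectors, sw * y)[, 1],
                xt = crossprod(eig$vectors, sw)[, 1])
  }
  v <- 1 + vc$gamma * rot$values
  iv <- 1 / v
  storage.mode(X) <- "double"
  Xt <- crossprod(rot$vectors, rot$sqrt_w * X)   # n x m rotated genotypes
  yt <- rot$yt; x0 <- rot$xt
  a00 <- sum(x0^2 * iv)
  b0 <- sum(x0 * yt * iv)
  yy <- sum(yt^2 * iv)
  a01 <- colSums(Xt * (x0 * iv))
  a11 <- colSums(Xt^2 * iv)
  b1 <- colSums(Xt * (yt * iv))
  det <- a00 * a11 - a01^2
  mono <- det <= .Machine$double.eps * a00 * pmax(a11, 1)
  det[mono] <- NA_real_
  ghat <- (a00 * b1 - a01 * b0) / det
  muhat <- (a11 * b0 - a01 * b1) / det
  rss <- yy - (muhat * b0 + ghat * b1)
  rss[rss < 0] <- 0
  s2 <- rss / (n - 2)
  se <- sqrt(s2 * a00 / det)
  tstat <- ghat / se
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[mono] <- 1
  p[p == 0] <- .Machine$double.xmin   # keep p in (0, 1]
  res <- data.frame(marker_id = colnames(X) %||% seq_len(m),
                    chromosome = if (is.null(map)) NA_integer_ else map$chromosome,
                    position_bp = if (is.null(map)) NA_integer_ else map$position_bp,
                    effect = ghat, se = se, t = tstat, p = p,
                    neg_log10_p = -log10(p),
                    monomorphic = mono, stringsAsFactors = FALSE)
  thr <- setNames(vapply(alpha, bonferroni_threshold, numeric(1),
                         n_markers = m), paste0("alpha_", alpha))
  for (a in alpha)
    res[[sprintf("significant_%g", a)]] <- res$p < a / m & !mono
  structure(list(results = res, vc = vc, n = n, m = m, alpha = alpha,
                 bonferroni = thr,
                 lambda = if (any(!mono))
                   genomic_inflation_lambda(res$p[!mono]) else NA_real_),
            class = "lmm_gwas")
}

#' @export
print.lmm_gwas <- function(x, ...) {
  cat(sprintf("Single-SNP weighted mixed-model scan: %d individuals, %d markers\n",
              x$n, x$m))
  cat(sprintf("  sigma2_u = %.4g, sigma2_e = %.4g (REML, fixed across markers)\n",
              x$vc$sigma2_u, x$vc$sigma2_e))
  for (i in seq_along(x$alpha))
    cat(sprintf("  Bonferroni -log10(p) threshold at alpha=%g: %.2f (%d significant)\n",
                x$alpha[i], x$bonferroni[i],
                sum(x$results[[sprintf("significant_%g", x$alpha[i])]])))
  cat(sprintf("  genomic inflation lambda = %.3f\n", x$lambda))
  invisible(x)
}

#' @export
summary.lmm_gwas <- function(object, n_top = 10, ...) {
  print(object)
  ord <- order(object$results$p)
  cat("\nTop markers:\n")
  print(object$results[head(ord, n_top),
                       c("marker_id", "chromosome", "position_bp", "effect",
                         "se", "t", "p", "neg_log10_p")],
        row.names = FALSE)
  invisible(object)
}

#' @export
coef.lmm_gwas <- function(object, ...) {
  setNames(object$results$effect, object$results$marker_id)
}

#' Manhattan plot of a mixed-model scan
#'
#' @param x an \code{lmm_gwas} fit.
#' @param ... passed to \code{plot}.
#' @export
plot.lmm_gwas <- function(x, ...) {
  r <- x$results
  if (all(is.na(r$chromosome))) {
    xs <- seq_len(nrow(r))
  } else {
    off <- c(0, cumsum(tapply(r$position_bp, r$chromosome, max)))
    xs <- r$position_bp + off[match(r$chromosome, sort(unique(r$chromosome)))]
  }
  graphics::plot(xs, r$neg_log10_p, pch = 20, cex = 0.5,
                 col = (r$chromosome %% 2) + 1,
                 xlab = "genome position", ylab = expression(-log[10](p)), ...)
  graphics::abline(h = x$bonferroni, col = c("red", "blue")[seq_along(x$bonferroni)],
                   lty = 2)
  invisible(x)
}

#' Bonferroni genome-wide significance threshold
#'
#' Returns the -log10(p) threshold for a family-wise level \code{alpha} over
#' \code{n_markers} tests, i.e. \code{-log10(alpha / n_markers)}.
#'
#' @param n_markers number of markers tested.
#' @param alpha nominal family-wise error level.
#' @return The threshold on the -log10(p) scale.
#' @export
bonferroni_threshold <- function(n_markers, alpha = 0.05) {
  stopifnot(n_markers >= 1, alpha > 0, alpha < 1)
  -log10(alpha / n_markers)
}

#' Genomic inflation factor (lambda)
#'
#' Median of the 1-df chi-square quantiles of the observed p-values divided
#' by the null median 0.4549364 (the median of a chi-square with one degree
#' of freedom).  Values well above 1 indicate residual population
#' stratification.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return The inflation factor lambda.
#' @export
genomic_inflation_lambda <- function(p_values) {
  if (length(p_values) == 0) stop("no p-values supplied")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must lie in (0, 1]")
  median(qchisq(p_values, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1)
}
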
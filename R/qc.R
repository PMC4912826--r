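#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the Hardy-Weinberg expectations n*p^2, 2*n*p*q, n*q^2, with the
#' allele frequency p estimated from the sample.  Monomorphic markers
#' (p = 0 or 1) return chi2 = 0 and p-value 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (vectorised).
#' @return \code{list(chi2, p)} with the statistic and upper-tail p-value.
#' @export
hwe_chi_square <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (any(n <= 0)) stop("total genotype count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  e_AA <- n * p^2
  e_Aa <- 2 * n * p * q
  e_aa <- n * q^2
  mono <- p == 0 | p == 1
  chi2 <- ifelse(mono, 0,
                 (n_AA - e_AA)^2 / e_AA + (n_Aa - e_Aa)^2 / e_Aa +
                   (n_aa - e_aa)^2 / e_aa)
  pval <- ifelse(mono, 1, pchisq(chi2, df = 1, lower.tail = FALSE))
  list(chi2 = chi2, p = pval)
}

#' Per-marker quality-control statistics
#'
#' Computes, for each marker, the minor allele frequency (on non-missing
#' calls), the call frequency (non-missing fraction), the mean GenCall score
#' (taken from the genotype matrix's \code{mean_gencall} attribute, 1 when
#' absent), the Hardy-Weinberg p-value from \code{\link{hwe_chi_square}}, and
#' a position flag.  Markers with zero non-missing calls get NA maf/hwe_p and
#' automatically fail filtering.
#'
#' @param genotypes n x m matrix coded 0/1/2 with NA for missing.
#' @param map optional marker map supplying positions (all markers count as
#'   positioned when omitted).
#' @return Data frame of class \code{marker_qc_stats} with columns
#'   \code{marker}, \code{maf}, \code{call_frequency}, \code{mean_gencall},
#'   \code{hwe_p}, \code{has_position}.
#' @export
compute_marker_stats <- function(genotypes, map = NULL) {
  m <- ncol(genotypes)
  n <- nrow(genotypes)
  n_obs <- colSums(!is.na(genotypes))
  call_frequency <- n_obs / n
  n0 <- colSums(genotypes == 0L, na.rm = TRUE)
  n1 <- colSums(genotypes == 1L, na.rm = TRUE)
  n2 <- colSums(genotypes == 2L, na.rm = TRUE)
  f2 <- ifelse(n_obs > 0, (n1 + 2 * n2) / (2 * n_obs), NA_real_)
  maf <- pmin(f2, 1 - f2)
  hwe_p <- rep(NA_real_, m)
  ok <- n_obs > 0
  if (any(ok)) hwe_p[ok] <- hwe_chi_square(n0[ok], n1[ok], n2[ok])$p
  gencall <- attr(genotypes, "mean_gencall") %||% rep(1, m)
  has_pos <- if (is.null(map)) rep(TRUE, m)
             else !is.na(map$position_bp) & map$position_bp >= 1
  structure(data.frame(marker = colnames(genotypes) %||% seq_len(m),
                       maf = maf, call_frequency = call_frequency,
                       mean_gencall = gencall, hwe_p = hwe_p,
                       has_position = has_pos, stringsAsFactors = FALSE),
            class = c("marker_qc_stats", "data.frame"))
}

#' Marker quality-control filter
#'
#' Keeps a marker iff maf > 0.01, call frequency > 0.9, mean GenCall > 0.60,
#' Hardy-Weinberg p > 1e-7 and it has a map position.  All inequalities are
#' strict; markers with undefined (NA) statistics fail.
#'
#' @param stats output of \code{\link{compute_marker_stats}}.
#' @param maf_min,call_freq_min,gencall_min,hwe_p_min filter thresholds.
#' @return Integer vector of kept marker indices.
#' @export
filter_markers <- function(stats, maf_min = 0.01, call_freq_min = 0.9,
                           gencall_min = 0.60, hwe_p_min = 1e-7) {
  keep <- !is.na(stats$maf) & stats$maf > maf_min &
    stats$call_frequency > call_freq_min &
    stats$mean_gencall > gencall_min &
    !is.na(stats$hwe_p) & stats$hwe_p > hwe_p_min &
    stats$has_position
  which(keep)
}

#' Animal call-rate filter
#'
#' Excludes individuals whose genotype call rate is strictly below
#' \code{min_call_rate} (default 0.8); a call rate of exactly 0.8 is kept.
#'
#' @param genotypes n x m genotype matrix with NA for missing.
#' @param min_call_rate exclusion threshold.
#' @return Integer vector of kept individual indices.
#' @export
filter_animals <- function(genotypes, min_call_rate = 0.8) {
  cr <- rowMeans(!is.na(genotypes))
  which(cr >= min_call_rate)
}

#' Naive mean imputation of missing genotypes
#'
#' Replaces each missing call with the marker's mean genotype rounded half-up
#' to the nearest of 0/1/2.  Non-missing entries are never altered.
#'
#' @param genotypes n x m genotype matrix with NA for missing.
#' @return The matrix with no missing values (attributes preserved).
#' @export
impute_missing_naive <- function(genotypes) {
  if (!anyNA(genotypes)) return(genotypes)
  n_obs <- colSums(!is.na(genotypes))
  if (any(n_obs == 0))
    stop("markers with all calls missing: filter them before imputation ",
         "(first offender column ", which(n_obs == 0)[1], ")")
  fill <- as.integer(pmin(2, pmax(0, floor(colMeans(genotypes, na.rm = TRUE) + 0.5))))
  idx <- which(is.na(genotypes), arr.ind = TRUE)
  genotypes[idx] <- fill[idx[, 2]]
  genotypes
}

#' Run the full genotype quality-control stage
#'
#' Animals are filtered first (call rate below 0.8 excluded), marker
#' statistics are then recomputed on the kept animals and the marker filter
#' applied, mirroring common chip-QC practice.
#'
#' @param genotypes n x m genotype matrix with NA for missing.
#' @param map marker map aligned with the columns.
#' @param maf_min,call_freq_min,gencall_min,hwe_p_min,min_call_rate thresholds.
#' @return \code{list(geno, map, kept_animals, kept_markers, report)} where
#'   \code{report} is a per-marker data frame with each statistic and a
#'   pass/fail reason.
#' @export
qc_genotypes <- function(genotypes, map = NULL, maf_min = 0.01,
                         call_freq_min = 0.9, gencall_min = 0.60,
                         hwe_p_min = 1e-7, min_call_rate = 0.8) {
  kept_animals <- filter_animals(genotypes, min_call_rate)
  sub <- genotypes[kept_animals, , drop = FALSE]
  attr(sub, "mean_gencall") <- attr(genotypes, "mean_gencall")
  stats <- compute_marker_stats(sub, map)
  kept_markers <- filter_markers(stats, maf_min, call_freq_min, gencall_min,
                                 hwe_p_min)
  reason <- rep("pass", nrow(stats))
  fail <- function(cond, why) reason <<- ifelse(reason == "pass" & cond, why, reason)
  fail(is.na(stats$maf) | stats$maf <= maf_min, "maf")
  fail(stats$call_frequency <= call_freq_min, "call_frequency")
  fail(stats$mean_gencall <= gencall_min, "mean_gencall")
  fail(is.na(stats$hwe_p) | stats$hwe_p <= hwe_p_min, "hwe")
  fail(!stats$has_position, "no_position")
  report <- cbind(stats, pass = seq_len(nrow(stats)) %in% kept_markers,
                  reason = reason)
  out <- sub[, kept_markers, drop = FALSE]
  attr(out, "mean_gencall") <- attr(sub, "mean_gencall")[kept_markers]
  comp <- attr(genotypes, "complete")
  if (!is.null(comp))
    attr(out, "complete") <- comp[kept_animals, kept_markers, drop = FALSE]
  list(geno = out,
       map = if (is.null(map)) NULL else map[kept_markers, , drop = FALSE],
       kept_animals = kept_animals, kept_markers = kept_markers,
       report = report)
}
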
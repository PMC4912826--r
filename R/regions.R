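#' Sliding windows over a marker map
#'
#' Anchors one window of \code{length_bp} at every marker position p, spanning
#' the half-open interval [p, p + length_bp) on that marker's chromosome
#' (maximal-resolution sliding; the window count equals the marker count).
#' Member markers are exactly those with start <= position < end.
#'
#' @param map marker map sorted by chromosome then position.
#' @param length_bp window length in base pairs (e.g. 1e6, 2.5e6, 5e6).
#' @param chrom_lengths optional named/indexed vector of chromosome lengths
#'   used to clip window ends.
#' @return Data frame of class \code{qw_windows}: chromosome, start_bp,
#'   end_bp, first_marker, last_marker (row indices into \code{map}),
#'   n_markers.
#' @export
build_windows <- function(map, length_bp, chrom_lengths = NULL) {
  stopifnot(length_bp >= 1)
  o <- order(map$chromosome, map$position_bp)
  if (any(o != seq_len(nrow(map))))
    stop("marker map must be sorted by chromosome and position (first ",
         "offending marker: ", map$marker_id[which(o != seq_len(nrow(map)))[1]], ")")
  if (any(duplicated(map[c("chromosome", "position_bp")])))
    stop("duplicated marker positions within a chromosome")
  first <- last <- integer(nrow(map))
  for (c_ in unique(map$chromosome)) {
    idx <- which(map$chromosome == c_)
    pos <- map$position_bp[idx]
    # last member of window anchored at pos[k]: largest pos < pos[k] + L
    lk <- findInterval(pos + length_bp - 0.5, pos)
    first[idx] <- idx[1] - 1L + seq_along(idx)
    last[idx] <- idx[1] - 1L + lk
  }
  end <- map$position_bp + length_bp
  if (!is.null(chrom_lengths))
    end <- pmin(end, chrom_lengths[map$chromosome] + 1)
  structure(data.frame(chromosome = map$chromosome,
                       start_bp = map$position_bp, end_bp = end,
                       first_marker = first, last_marker = last,
                       n_markers = last - first + 1L),
            class = c("qw_windows", "data.frame"))
}

#' Window posterior probability PP_int
#'
#' For each window, PP_int is the proportion of saved MCMC cycles in which at
#' least one member SNP falls into the large-effect mixture component
#' (delta = 1).  Computed by per-cycle cumulative sums over the (sorted)
#' marker axis, which is exactly equivalent to the per-window, per-cycle
#' definition.
#'
#' @param windows output of \code{\link{build_windows}}.
#' @param delta_samples T x m binary matrix of saved mixture indicators (or a
#'   \code{bayes_mixture} fit).
#' @return The windows data frame with a \code{pp_int} column added.
#' @export
compute_pp_int <- function(windows, delta_samples) {
  if (inherits(delta_samples, "bayes_mixture"))
    delta_samples <- delta_samples$samples$delta
  if (nrow(delta_samples) < 1) stop("no saved cycles: cannot compute PP_int")
  cs <- cbind(0L, t(apply(delta_samples, 1, cumsum)))  # T x (m+1)
  pp <- vapply(seq_len(nrow(windows)), function(k) {
    cnt <- cs[, windows$last_marker[k] + 1L] - cs[, windows$first_marker[k]]
    mean(cnt > 0L)
  }, numeric(1))
  windows$pp_int <- pp
  windows
}

#' Candidate peaks from the PP_int track
#'
#' Windows with PP_int strictly above the threshold are grouped into maximal
#' chains of windows that overlap or touch in base pairs on the same
#' chromosome; every chain is one candidate peak.  An empty result (no window
#' above the threshold) is valid and mirrors the "no significant region
#' detected" outcome.
#'
#' @param windows windows with a \code{pp_int} column.
#' @param threshold PP_int significance threshold (default 0.8).
#' @return List of data frames, one per peak (class \code{qw_peaks}).
#' @export
find_candidate_peaks <- function(windows, threshold = 0.8) {
  stopifnot(!is.null(windows$pp_int))
  hot <- windows[windows$pp_int > threshold, , drop = FALSE]
  if (nrow(hot) == 0) return(structure(list(), class = "qw_peaks"))
  hot <- hot[order(hot$chromosome, hot$start_bp), , drop = FALSE]
  grp <- integer(nrow(hot))
  gid <- 1L
  grp[1] <- gid
  run_end <- hot$end_bp[1]
  for (k in seq_len(nrow(hot))[-1]) {
    if (hot$chromosome[k] != hot$chromosome[k - 1] || hot$start_bp[k] > run_end) {
      gid <- gid + 1L
      run_end <- hot$end_bp[k]
    } else run_end <- max(run_end, hot$end_bp[k])
    grp[k] <- gid
  }
  structure(split(hot, grp), class = "qw_peaks")
}

#' Select one QTL region per candidate peak
#'
#' Within each peak the window with the highest PP_int is chosen as the QTL
#' region; ties are broken toward the smallest start position.
#'
#' @param peaks output of \code{\link{find_candidate_peaks}}.
#' @return Data frame of selected regions (possibly zero rows).
#' @export
select_regions <- function(peaks) {
  if (length(peaks) == 0)
    return(data.frame(chromosome = integer(0), start_bp = numeric(0),
                      end_bp = numeric(0), first_marker = integer(0),
                      last_marker = integer(0), n_markers = integer(0),
                      pp_int = numeric(0)))
  picked <- lapply(peaks, function(pk) {
    best <- which(pk$pp_int == max(pk$pp_int))
    best <- best[which.min(pk$start_bp[best])]
    pk[best, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

#' Posterior genetic variance of a QTL region
#'
#' For every saved cycle t the region variance is the population variance
#' (denominator n) across individuals of X_region g_region^(t); reported are
#' its posterior mean and SD, together with the mean proportion of additive
#' genetic variance it explains.  By default the per-cycle total is the
#' variance of the full genomic value plus the polygenic effect
#' (X g^(t) + u^(t)); set \code{denominator = "markers"} for the marker-only
#' alternative.  Cycles with zero total variance are skipped (their count is
#' reported).
#'
#' @param region one row of \code{\link{select_regions}} output (or any list
#'   with \code{first_marker}/\code{last_marker}).
#' @param genotypes n x m genotype matrix used in the fit.
#' @param fit a \code{bayes_mixture} object (or its \code{samples} list).
#' @param denominator "genomic_plus_polygenic" (default) or "markers".
#' @return \code{list(mean, sd, proportion, n_skipped)}.
#' @export
region_variance <- function(region, genotypes, fit,
                            denominator = c("genomic_plus_polygenic", "markers")) {
  denominator <- match.arg(denominator)
  s <- if (inherits(fit, "bayes_mixture")) fit$samples else fit
  obs <- if (inherits(fit, "bayes_mixture")) fit$obs_index else seq_len(nrow(genotypes))
  jj <- seq(region$first_marker, region$last_marker)
  Xr <- genotypes[, jj, drop = FALSE]
  gv_r <- Xr %*% t(s$g[, jj, drop = FALSE])       # n x T
  v_r <- apply(gv_r, 2, pop_var)
  gv_all <- genotypes %*% t(s$g)
  if (denominator == "genomic_plus_polygenic")
    gv_all <- gv_all + t(s$u[, obs, drop = FALSE])
  v_tot <- apply(gv_all, 2, pop_var)
  keep <- v_tot > 0
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    warning(n_skipped, " cycles with zero total genetic variance skipped")
  list(mean = mean(v_r), sd = sd(v_r),
       proportion = if (any(keep)) mean(v_r[keep] / v_tot[keep]) else NA_real_,
       n_skipped = n_skipped)
}

#' Sliding-window QTL region scan of a mixture-model fit
#'
#' Runs the full post-MCMC region analysis for one or more window lengths:
#' builds marker-anchored sliding windows, computes the window posterior
#' probability PP_int, groups above-threshold windows into candidate peaks,
#' selects the highest-PP_int window of each peak as the QTL region and
#' summarises each region's posterior genetic variance.
#'
#' @param fit a \code{\link{bayes_mixture}} object carrying a marker map.
#' @param window_bp vector of window lengths in bp (default 1.0, 2.5, 5.0 Mb).
#' @param threshold PP_int significance threshold (default 0.8).
#' @param map optional map overriding the one stored in the fit.
#' @param chrom_lengths optional chromosome lengths for window clipping.
#' @param denominator total-variance definition for the explained proportion,
#'   see \code{\link{region_variance}}.
#' @return Object of class \code{qtl_regions}: per-length window tracks and a
#'   combined region report (chromosome, start, end, length, PP_int, variance
#'   mean/SD, proportion of additive genetic variance).
#' @export
qtl_regions <- function(fit, window_bp = c(1e6, 2.5e6, 5e6), threshold = 0.8,
                        map = NULL, chrom_lengths = NULL,
                        denominator = "genomic_plus_polygenic") {
  stopifnot(inherits(fit, "bayes_mixture"))
  map <- map %||% fit$map
  if (is.null(map)) stop("a marker map is required for region scanning")
  stopifnot(threshold > 0, threshold <= 1)
  tracks <- list()
  reports <- list()
  for (L in window_bp) {
    win <- build_windows(map, L, chrom_lengths)
    win <- compute_pp_int(win, fit)
    tracks[[sprintf("%g", L)]] <- win
    regs <- select_regions(find_candidate_peaks(win, threshold))
    if (nrow(regs) > 0) {
      vs <- lapply(seq_len(nrow(regs)), function(k)
        region_variance(regs[k, ], fit$genotypes, fit, denominator))
      regs$length_bp <- L
      regs$variance_mean <- vapply(vs, `[[`, 0, "mean")
      regs$variance_sd <- vapply(vs, `[[`, 0, "sd")
      regs$variance_proportion <- vapply(vs, `[[`, 0, "proportion")
      reports[[sprintf("%g", L)]] <- regs
    }
  }
  regions <- if (length(reports)) do.call(rbind, c(reports, make.row.names = FALSE))
             else data.frame()
  structure(list(tracks = tracks, regions = regions, threshold = threshold,
                 window_bp = window_bp),
            class = "qtl_regions")
}

#' @export
print.qtl_regions <- function(x, ...) {
  cat(sprintf("QTL region scan (PP_int threshold %.2f, window lengths: %s bp)\n",
              x$threshold, paste(format(x$window_bp, big.mark = ","),
                                 collapse = ", ")))
  if (nrow(x$regions) == 0) {
    cat("  no significant region was detected\n")
  } else {
    cols <- c("chromosome", "start_bp", "end_bp", "length_bp", "pp_int",
              "variance_mean", "variance_sd", "variance_proportion")
    print(x$regions[, cols], row.names = FALSE)
  }
  invisible(x)
}

#' PP_int track plot
#'
#' @param x a \code{qtl_regions} object.
#' @param window which window-length track to draw (index or name).
#' @param ... passed to \code{plot}.
#' @export
plot.qtl_regions <- function(x, window = 1, ...) {
  tr <- x$tracks[[window]]
  off <- c(0, cumsum(tapply(tr$end_bp, tr$chromosome, max)))
  xs <- tr$start_bp + off[match(tr$chromosome, sort(unique(tr$chromosome)))]
  graphics::plot(xs, tr$pp_int, type = "p", pch = 20, cex = 0.5,
                 col = (tr$chromosome %% 2) + 1, ylim = c(0, 1),
                 xlab = "genome position", ylab = expression(PP[int]), ...)
  graphics::abline(h = x$threshold, col = "red", lty = 2)
  invisible(x)
}
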
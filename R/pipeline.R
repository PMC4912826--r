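#' Write a dataset in the package's plain-text dialect
#'
#' Writes PLINK-style \code{<prefix>.map} (chromosome, marker_id, 0,
#' position), a transposed genotype matrix \code{<prefix>.geno.tsv}
#' (markers as rows, individuals as columns, missing coded "NA"), a pedigree
#' CSV (id, sire, dam; 0 = unknown), a phenotype TSV (id, trait, y_c,
#' weight) and, when truth is supplied, a \code{truth.json}.
#'
#' @param dataset list as returned by \code{\link{simulate_dataset}} (any of
#'   pedigree/phenotypes/truth may be NULL).
#' @param prefix output path prefix (directories are created).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  map <- dataset$map
  f <- paste0(prefix, ".map")
  write.table(data.frame(map$chromosome, map$marker_id, 0, map$position_bp),
              f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  files <- c(files, f)
  g <- dataset$geno
  tg <- t(g)
  out <- data.frame(marker_id = map$marker_id, tg, check.names = FALSE,
                    stringsAsFactors = FALSE)
  colnames(out) <- c("marker_id", rownames(g) %||% seq_len(nrow(g)))
  f <- paste0(prefix, ".geno.tsv")
  write.table(out, f, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  files <- c(files, f)
  if (!is.null(dataset$pedigree)) {
    f <- paste0(prefix, ".pedigree.csv")
    write.table(dataset$pedigree[c("id", "sire", "dam")], f, sep = ",",
                quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(dataset$phenotypes)) {
    f <- paste0(prefix, ".pheno.tsv")
    write.table(dataset$phenotypes, f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(dataset$truth)) {
    f <- paste0(prefix, ".truth.json")
    jsonlite::write_json(dataset$truth, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read genotypes written by \code{\link{write_dataset}}
#'
#' @param prefix path prefix of the \code{.map} / \code{.geno.tsv} pair.
#' @return \code{list(map, geno)} with individuals as genotype rows; the
#'   round trip with the writer is lossless.
#' @export
read_genotypes <- function(prefix) {
  mf <- paste0(prefix, ".map")
  gf <- paste0(prefix, ".geno.tsv")
  for (f in c(mf, gf)) if (!file.exists(f)) stop("missing input file: ", f)
  mp <- read.table(mf, sep = "\t", header = FALSE,
                   col.names = c("chromosome", "marker_id", "cm", "position_bp"),
                   stringsAsFactors = FALSE)
  map <- data.frame(marker_id = mp$marker_id, chromosome = mp$chromosome,
                    position_bp = mp$position_bp, allele_1 = "A",
                    allele_2 = "B", stringsAsFactors = FALSE)
  if (anyDuplicated(map$marker_id))
    stop("duplicate marker ids in map: ",
         map$marker_id[which(duplicated(map$marker_id))[1]])
  o <- order(map$chromosome, map$position_bp)
  if (any(o != seq_len(nrow(map))))
    stop("marker map is not sorted by chromosome and position (first ",
         "offending marker: ",
         map$marker_id[which(o != seq_len(nrow(map)))[1]], ")")
  raw <- readLines(gf)
  header <- strsplit(raw[1], "\t", fixed = TRUE)[[1]]
  ids <- header[-1]
  body <- strsplit(raw[-1], "\t", fixed = TRUE)
  nfield <- lengths(body)
  if (any(nfield != length(header)))
    stop("malformed genotype line ", which(nfield != length(header))[1] + 1L,
         ": expected ", length(header), " fields")
  mk <- vapply(body, `[[`, "", 1L)
  if (!identical(mk, map$marker_id))
    stop("genotype rows do not match map marker order")
  vals <- vapply(body, function(x) {
    v <- suppressWarnings(as.integer(x[-1]))
    bad <- which(is.na(v) & x[-1] != "NA")
    if (length(bad)) stop("malformed genotype value '", x[-1][bad[1]], "'")
    v
  }, integer(length(ids)))
  geno <- vals                  # vapply over markers gives individuals x markers
  dimnames(geno) <- list(ids, map$marker_id)
  if (any(!is.na(geno) & !(geno %in% 0:2)))
    stop("genotype values outside {0,1,2,NA}")
  list(map = map, geno = geno)
}

#' Read a pedigree CSV (id, sire, dam; 0 = unknown)
#' @param path file path.
#' @return Pedigree data frame.
#' @export
read_pedigree <- function(path) {
  pd <- read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "sire", "dam") %in% names(pd)))
  pd
}

#' Read a phenotype TSV (id, trait, y_c, weight)
#' @param path file path.
#' @return Phenotype data frame.
#' @export
read_phenotypes <- function(path) {
  ph <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "y_c", "weight") %in% names(ph)))
  if (any(ph$weight <= 0)) stop("phenotype weights must be strictly positive")
  ph
}

#' Pipeline configuration
#'
#' Gathers the paths and settings for an end-to-end run: QC thresholds,
#' nominal levels for the mixed-model scan, the Gibbs chain block, region-scan
#' window lengths and PP_int threshold, and the RNG seed.  Defaults are the
#' standard analysis settings (QC: maf > 0.01, call frequency > 0.9, GenCall
#' > 0.60, HWE p > 1e-7, animal call rate >= 0.8; chain 52,000/20,000/20;
#' windows 1.0/2.5/5.0 Mb; PP_int threshold 0.8).
#'
#' @param prefix input path prefix (as written by \code{\link{write_dataset}}).
#' @param out_dir output directory for reports and tracks.
#' @param qc named list overriding QC thresholds.
#' @param alpha nominal Bonferroni levels.
#' @param chain a \code{\link{gibbs_config}}.
#' @param window_bp region-scan window lengths (bp).
#' @param pp_threshold PP_int significance threshold in (0, 1].
#' @param seed integer seed for the chain.
#' @return Validated list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(prefix, out_dir, qc = list(), alpha = c(0.05, 0.01),
                            chain = gibbs_config(), window_bp = c(1e6, 2.5e6, 5e6),
                            pp_threshold = 0.8, seed = 1) {
  qc_full <- modifyList(list(maf_min = 0.01, call_freq_min = 0.9,
                             gencall_min = 0.60, hwe_p_min = 1e-7,
                             min_call_rate = 0.8), qc)
  if (!(pp_threshold > 0 && pp_threshold <= 1))
    stop("pp_threshold must lie in (0, 1]")
  if (!all(alpha > 0 & alpha < 1)) stop("alpha levels must lie in (0, 1)")
  if (!all(window_bp >= 1)) stop("window lengths must be >= 1 bp")
  stopifnot(inherits(chain, "gibbs_config"))
  structure(list(prefix = prefix, out_dir = out_dir, qc = qc_full,
                 alpha = alpha, chain = chain, window_bp = window_bp,
                 pp_threshold = pp_threshold, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes QC and imputation, the REML + single-SNP mixed-model scan, the
#' Bayesian mixture-model Gibbs chain and the sliding-window region scan for
#' every configured window length, writing to the output directory: a QC
#' report, the association TSV, scalar chain samples, per-marker posterior
#' summaries, one PP_int track per window length, the region report and a log
#' with seed, package version, thresholds and counts.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return Invisibly, a list with the fitted objects and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("qtlwin pipeline, package version %s", packageVersion("qtlwin"))
  logline("seed: %d", config$seed)
  logline("qc thresholds: %s",
          paste(names(config$qc), unlist(config$qc), sep = "=", collapse = ", "))
  logline("chain: %d cycles, %d burn-in, thin %d", config$chain$n_cycles,
          config$chain$burn_in, config$chain$thin)
  jsonlite::write_json(unclass(config)[c("prefix", "out_dir", "qc", "alpha",
                                         "window_bp", "pp_threshold", "seed")],
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  stage <- "read"
  res <- tryCatch({
    gt <- read_genotypes(config$prefix)
    ped <- read_pedigree(paste0(config$prefix, ".pedigree.csv"))
    ph <- read_phenotypes(paste0(config$prefix, ".pheno.tsv"))

    stage <- "qc"
    qc <- qc_genotypes(gt$geno, gt$map, config$qc$maf_min,
                       config$qc$call_freq_min, config$qc$gencall_min,
                       config$qc$hwe_p_min, config$qc$min_call_rate)
    write.table(qc$report, file.path(config$out_dir, "qc_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    logline("qc: kept %d/%d animals, %d/%d markers",
            length(qc$kept_animals), nrow(gt$geno),
            length(qc$kept_markers), ncol(gt$geno))

    stage <- "imputation"
    geno <- impute_missing_naive(qc$geno)
    ids <- rownames(geno) %||% as.character(seq_len(nrow(geno)))
    ph <- ph[match(ids, as.character(ph$id)), ]
    if (anyNA(ph$y_c)) stop("phenotypes missing for some genotyped animals")

    stage <- "lmm_scan"
    A_all <- build_relationship_matrix(ped)
    ai <- match(ids, as.character(ped$id))
    if (anyNA(ai)) stop("genotyped animals missing from pedigree")
    A <- A_all[ai, ai]
    lm_fit <- lmm_gwas(ph$y_c, geno, A, ph$weight, qc$map,
                       alpha = config$alpha)
    write.table(lm_fit$results, file.path(config$out_dir, "association.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    logline("lmm: lambda = %.4f; significant at %s: %s", lm_fit$lambda,
            paste(config$alpha, collapse = "/"),
            paste(vapply(config$alpha, function(a)
              sum(lm_fit$results[[sprintf("significant_%g", a)]]), 0L),
              collapse = "/"))

    stage <- "bayes_mixture"
    chain <- config$chain
    chain$seed <- chain$seed %||% config$seed
    bm <- bayes_mixture(ph$y_c, geno, pedigree = ped, weights = ph$weight,
                        chain = chain, map = qc$map, obs_index = ai)
    ps <- posterior_summaries(bm)
    write.table(cbind(cycle = seq_len(bm$samples$n_saved),
                      mu = bm$samples$mu, sigma2_g0 = bm$samples$sigma2_g0,
                      pi0 = bm$samples$pi0, sigma2_u = bm$samples$sigma2_u,
                      sigma2_e = bm$samples$sigma2_e),
                file.path(config$out_dir, "chain_scalars.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ps$markers, file.path(config$out_dir, "posterior_markers.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    logline("bm: %d saved cycles, posterior mean pi0 = %.4f",
            bm$samples$n_saved, mean(bm$samples$pi0))

    stage <- "region_scan"
    rs <- qtl_regions(bm, config$window_bp, config$pp_threshold)
    for (nm in names(rs$tracks)) {
      tr <- rs$tracks[[nm]]
      write.table(tr[c("chromosome", "start_bp", "end_bp", "n_markers",
                       "pp_int")],
                  file.path(config$out_dir,
                            sprintf("pp_track_%sbp.tsv", nm)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    rep_file <- file.path(config$out_dir, "region_report.tsv")
    if (nrow(rs$regions) > 0) {
      write.table(rs$regions[c("chromosome", "start_bp", "end_bp",
                               "length_bp", "pp_int", "variance_mean",
                               "variance_sd", "variance_proportion")],
                  rep_file, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      write.table(data.frame(chromosome = integer(0), start_bp = integer(0),
                             end_bp = integer(0), length_bp = integer(0),
                             pp_int = numeric(0), variance_mean = numeric(0),
                             variance_sd = numeric(0),
                             variance_proportion = numeric(0)),
                  rep_file, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    logline("regions: %d selected", nrow(rs$regions))
    list(qc = qc, lmm = lm_fit, bm = bm, regions = rs,
         out_dir = config$out_dir)
  }, error = function(e) {
    logline("FAILED at stage '%s': %s", stage, conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
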
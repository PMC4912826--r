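# qtlwin

Bayesian mixture-model GWAS with sliding-window QTL region detection, for
weighted corrected phenotypes in pedigreed populations (pig-style chip data).

Association scans that fit one SNP at a time struggle when many markers in LD
tag the same QTL: single-marker posterior probabilities are diluted and
neighbouring QTL blur into one peak. `qtlwin` implements a two-model analysis
for this setting:

* **`lmm_gwas()`** — a single-SNP weighted linear mixed model
  `y_c = 1mu + x g + Z u + e`, with a pedigree polygenic effect
  `u ~ N(0, A sigma2_u)` and heteroscedastic residuals
  `e ~ N(0, D sigma2_e)`, `D = diag(1/w_i)`. Variance components come from
  exact eigendecomposition-based REML on the null model and are held fixed
  across markers (two-stage GLS scan); effects are tested by two-sided
  t-tests with Bonferroni thresholds `-log10(alpha/N)`, and the genomic
  inflation factor lambda is reported.
* **`bayes_mixture()`** — a Bayesian mixture model fitting all SNPs
  simultaneously by Gibbs sampling: each effect is
  `N(0, sigma2_g0)` with probability `pi0` or `N(0, 100 * sigma2_g0)`
  otherwise, `pi0 ~ Beta(100, 1)`, with the same polygenic term and weights.
  The sampler (C++) draws each indicator with the effect integrated out and
  updates the polygenic vector through the sparse pedigree-built inverse of A.
* **`qtl_regions()`** — the post-MCMC region analysis: sliding windows of
  1.0/2.5/5.0 Mb anchored at every marker, the window posterior probability
  `PP_int` = fraction of saved cycles in which at least one window SNP falls
  in the large-effect component, candidate peaks above the 0.8 threshold, the
  highest-`PP_int` window per peak as the QTL region, and per-region posterior
  variance summaries `var(X_region g_region^(t))`.

Marker/animal quality control (`qc_genotypes()`), naive mean imputation, a
pedigree-based simulator with planted QTL (`simulate_dataset()`), plain-text
PLINK-style I/O and an end-to-end `run_pipeline()` complete the package.
Everything is reproducible bit-for-bit given a seed.

## Worked example

```r
library(qtlwin)

cfg <- sim_config(seed = 11)     # 1,000 pigs, 2,000 SNPs on 4 chromosomes,
d   <- simulate_dataset(cfg)     # 4 planted QTL on chromosomes 1-2

scan <- lmm_gwas(d$phenotypes$y_c, d$geno, d$A, d$phenotypes$weight, d$map)
print(scan)
#> Single-SNP weighted mixed-model scan: 1000 individuals, 2000 markers
#>   sigma2_u = 1.404, sigma2_e = 0.8134 (REML, fixed across markers)
#>   Bonferroni -log10(p) threshold at alpha=0.05: 4.60 (63 significant)
#>   Bonferroni -log10(p) threshold at alpha=0.01: 5.30 (62 significant)
#>   genomic inflation lambda = 1.143

bm <- bayes_mixture(d$phenotypes$y_c, d$geno, pedigree = d$pedigree,
                    weights = d$phenotypes$weight, map = d$map,
                    chain = gibbs_config(5200, 2000, 2, seed = 1))
regions <- qtl_regions(bm, window_bp = 1e6)
print(regions)
#> QTL region scan (PP_int threshold 0.80, window lengths: 1e+06 bp)
#>  chromosome start_bp   end_bp length_bp pp_int variance_mean variance_sd
#>           1  9146726 10146726     1e+06      1     0.2645850  0.04187951
#>           1 65776526 66776526     1e+06      1     0.1971595  0.03139228
#>           2 54651071 55651071     1e+06      1     0.1960206  0.04710526
#>           2 96121923 97121923     1e+06      1     0.1851692  0.03637693
#>  variance_proportion
#>            0.1926071
#>            0.1436413
#>            0.1426962
#>            0.1349281
```

All four detected 1-Mb regions contain a planted QTL
(`d$truth$true_region_spans`), each with posterior probability `PP_int = 1`
and explaining 13–19% of the additive genetic variance; the QTL-free
chromosomes 3 and 4 produce no window above the 0.8 threshold. A `PP_int`
track for plotting is in `regions$tracks`, and `plot(regions)` draws it.

The same analysis runs from files via `write_dataset()` /
`pipeline_config()` / `run_pipeline()`, or from a shell through the thin
wrapper `inst/scripts/qtlwin-pipeline.R`.

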
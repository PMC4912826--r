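---
title: "Mixture-model GWAS and sliding-window QTL region detection with qtlwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture-model GWAS and sliding-window QTL region detection with qtlwin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlwin)
```

## The problem

Genome-wide association studies in livestock commonly analyse *corrected
phenotypes* $y_c$ — trait records pre-adjusted for herd, season, parity and
other non-genetic effects — for pedigreed animals genotyped on a medium-density
SNP chip. Each record carries a reliability weight $w_i$, and close relatives
share genetic background that must be modelled to avoid spurious association.
`qtlwin` implements two complementary analyses of such data and a
post-MCMC procedure that turns marker-level posterior output into QTL
*regions*, plus a simulator that generates complete pig-like datasets so the
whole pipeline can be exercised and validated without any proprietary data.

## Single-SNP weighted linear mixed model

For one SNP at a time the model is

$$\mathbf{y}_c = \mathbf{1}\mu + \mathbf{x}g + \mathbf{Z}\mathbf{u} + \mathbf{e},
\qquad \mathbf{u} \sim N(\mathbf{0}, \mathbf{A}\sigma^2_u), \qquad
\mathbf{e} \sim N(\mathbf{0}, \mathbf{D}\sigma^2_e),$$

with $\mathbf{x}$ the 0/1/2 allele counts, $\mathbf{A}$ the pedigree-based
additive relationship matrix (tabular method) and
$\mathbf{D} = \mathrm{diag}(1/w_i)$, so a doubly reliable record has half the
residual variance. Effects are tested with a two-sided $t$-test on $n-2$
degrees of freedom and genome-wide significance uses Bonferroni thresholds
$-\log_{10}(\alpha/N)$ at $\alpha = 0.05$ and $0.01$.

Two numerical choices matter:

* **Variance components are estimated once** on the null (no-SNP) model by
  REML and held fixed across markers, the standard two-stage strategy for
  dense scans. Rather than iterative average-information updates we compute
  the *exact* REML optimum: one eigendecomposition of
  $\mathbf{W}^{1/2}\mathbf{A}\mathbf{W}^{1/2}$ reduces the likelihood to a
  one-dimensional function of $\gamma = \sigma^2_u/\sigma^2_e$, profiled in
  closed form over $\mu$ and $\sigma^2_e$ and maximised by Brent search.
  This has no convergence-failure modes and the boundary $\gamma = 0$ is
  checked explicitly; when the boundary fits within $10^{-6}$ log-likelihood
  units of the interior optimum it is preferred, which also resolves the
  non-identified case $\mathbf{A} = \mathbf{I}$ where only
  $\sigma^2_u + \sigma^2_e$ is estimable.
* **Per-marker residual rescaling.** The GLS fit for each marker re-estimates
  the residual scale from the whitened residuals on $n-2$ degrees of freedom.
  This makes the scan collapse *exactly* to ordinary least squares when
  $\sigma^2_u = 0$ and all weights are one, and makes the $t$-statistics
  invariant to any joint rescaling of the covariance structure.

The genomic inflation factor is
$\lambda = \mathrm{median}\{F^{-1}_{\chi^2_1}(1 - p_j)\} / 0.4549364$; values
well above one indicate residual stratification (the single-SNP model corrects
family structure only through the polygenic term).

## Bayesian two-component mixture model

The second model fits **all** markers simultaneously:

$$\mathbf{y}_c = \mathbf{1}\mu + \sum_{j=1}^m \mathbf{x}_j g_j +
\mathbf{Z}\mathbf{u} + \mathbf{e},$$

with the mixture prior

$$g_j \sim \begin{cases} N(0, \sigma^2_{g_0}) & \text{with probability } \pi_0\\
N(0, \sigma^2_{g_1}),\; \sigma^2_{g_1} = 100\,\sigma^2_{g_0} &
\text{with probability } 1 - \pi_0,\end{cases}$$

$\pi_0 \sim \mathrm{Beta}(100, 1)$ (prior mean $\approx 0.99$: most effects
small, a few large), flat priors on $\mu$ and $\sigma^2_{g_0}$, and the same
weighted residual structure and pedigree polygenic term as the linear mixed
model. The per-marker indicator $\delta_j$ ($1$ = large-effect component) is
the quantity everything downstream consumes.

The Gibbs sampler (C++, single-site updates) makes these choices:

* $(\delta_j, g_j)$ are updated **jointly**: $\delta_j$ is drawn with $g_j$
  integrated out of the likelihood, then $g_j$ from its normal conditional.
  The marginalised update mixes far better than conditioning on the current
  $g_j$ and leaves the stationary distribution unchanged.
* Genotype columns are **centred** internally, so the intercept and marker
  effects are orthogonal and a zero-variance marker has a genuinely flat
  likelihood (its inclusion frequency then equals the prior mean
  $1/101 \approx 0.0099$, a property the tests check).
* Under the flat prior the $\sigma^2_{g_0}$ conditional is inverse-gamma with
  shape $m/2 - 1$ and scale
  $\tfrac12\big(\sum_{\delta_j=0} g_j^2 + \sum_{\delta_j=1} g_j^2/100\big)$,
  proper only for $m \ge 4$; a finite support bound
  (`sigma2_g0_max`, default $100\,\mathrm{var}(y)$) keeps it proper in
  general, and for tiny $m$ the draw falls back to slice sampling on the
  bounded support. With only a handful of markers there are no null effects
  to pin the small-effect variance down, so the bound *is* the prior
  information; degenerate fixtures (e.g. the one-strong-marker test) set it
  to a small-effect scale explicitly.
* $\sigma^2_u$ and $\sigma^2_e$ get flat priors (consistent with the stated
  uniform priors on $\mu$ and $\sigma^2_{g_0}$), giving scaled
  inverse-chi-square-form conditionals; $\pi_0$ is conjugate
  Beta$(100 + m_0, 1 + m_1)$.
* The polygenic vector is updated element-wise through the **sparse inverse**
  of $\mathbf{A}$, built directly from the pedigree by Henderson's rules with
  the inbreeding correction — no dense factorisation enters the chain.
* Residuals are maintained by add-back/subtract updates and refreshed from
  scratch every `check_every` cycles; the maximum drift between the
  maintained and recomputed residual is reported with the fit (order
  $10^{-14}$ in practice, tested below $10^{-6}$).
* The weights enter the mixture model exactly as in the LM
  ($\mathrm{var}(e_i) = \sigma^2_e / w_i$); both models analyse the same
  weighted records.
* All randomness comes from R's RNG, so a `seed` in `gibbs_config()` makes
  chains bit-reproducible.

The reference chain protocol is 52,000 cycles, 20,000 burn-in, thinning 20 —
exactly 1,600 saved samples. Simulation experiments in this package use a
scaled-down 5,200 / 2,000 / 2 protocol (also 1,600 saved samples), which is
ample for the posterior probabilities of interest at the simulated data sizes.

## QTL regions from sliding-window posterior probabilities

Single-marker posterior inclusion probabilities are diluted when several
markers in LD share a signal. The region analysis therefore works on
*windows*: for window $W$ and saved cycles $t = 1,\dots,T$,

$$PP_{int}(W) = \frac1T \sum_{t=1}^T
\mathbf{1}\{\exists j \in W : \delta_j^{(t)} = 1\},$$

the posterior probability that the window contains at least one large-effect
SNP. The procedure is:

1. **Windows**: one window of length 1.0, 2.5 or 5.0 Mb anchored at *every*
   marker position $p$, spanning $[p, p + L)$ (half-open, 1-based). Anchoring
   at markers gives maximal resolution and one window per marker; the
   effective sliding step is therefore the inter-marker spacing. Because any
   enlargement of a window can only add members, $PP_{int}$ is monotone in
   the window length — the plateau where it stops increasing indicates the
   signal is fully captured.
2. **Candidate peaks**: windows with $PP_{int}$ strictly above the threshold
   (0.8 by default, a direct posterior probability the investigator may
   change) are grouped into maximal chains of windows that overlap or touch.
3. **Region selection**: in each peak the window with the highest $PP_{int}$
   is the QTL region; ties break toward the smallest start position.
4. **Region variance**: for each saved cycle,
   $v^{(t)} = \mathrm{var}(\mathbf{X}_{W}\, \mathbf{g}_{W}^{(t)})$ (population
   variance across individuals, denominator $n$); the posterior mean and SD
   are reported. The *proportion of additive genetic variance* divides by the
   per-cycle variance of the full genomic value plus the polygenic effect,
   $\mathrm{var}(\mathbf{X}\mathbf{g}^{(t)} + \mathbf{u}^{(t)})$ — the total
   is not uniquely defined by convention, so a marker-only denominator is
   available as an option. Cycles with zero total variance are skipped and
   counted.

An empty region set is a valid outcome and prints as
"no significant region was detected".

## The synthetic-data generator

The simulator emulates the structure of a medium-density pig dataset and
provides full ground truth:

* **Pedigree**: discrete generations; each generation randomly pairs the
  previous one into disjoint couples with a fixed litter size. Defaults (250
  founders, 3 generations of 250) give 1,000 individuals.
* **Genotypes**: founder haplotypes follow a first-order Markov chain along
  each chromosome — an allele copies its neighbour with probability
  $1 - d$ (`ld_decay` $= d$) or is drawn fresh at that marker's founder
  frequency (uniform on `maf_spectrum`). Meiosis recombines parental
  haplotypes with one uniformly placed crossover per chromosome. This is the
  simplest mechanism that creates multi-marker signals inside windows; it is
  not coalescent-grade population genetics. With strong LD the realised
  marker frequencies are smoothed toward their neighbours', so the frequency-
  spectrum checks run at `ld_decay = 1`. Missing calls are inserted
  independently at `missing_rate`; per-marker mean GenCall scores are drawn
  Beta(20, 2) (only their mean is consumed by QC, so the distributional
  choice is immaterial).
* **Phenotypes**: `n_qtl` markers (minor allele frequency $\ge 0.1$,
  restricted to `qtl_chromosomes`, pairwise at least `qtl_min_gap_bp` apart)
  receive alternating-sign effects rescaled *post hoc* so the planted QTL
  explain exactly `qtl_variance_fraction` of the additive genetic variance
  in-sample, where the additive total is the planted marker variance plus the
  polygenic variance $\sigma^2_u$ — this makes recovery experiments exactly
  calibrated. Ground truth records the QTL positions as point spans; a
  detected window "recovers" a QTL when it contains the planted position.
  Polygenic values are drawn $N(\mathbf{0}, \mathbf{A}\sigma^2_u)$, weights
  uniform on `weight_range`, residuals $N(0, \sigma^2_e/w_i)$.

Defaults are the package's standard study conditions: 4 chromosomes of
100 Mb with 500 markers each (2,000 markers), 4 QTL on chromosomes 1–2 (so
chromosomes 3–4 stay QTL-free for false-positive accounting),
`qtl_variance_fraction` 0.77 with $\sigma^2_u = 0.3$, $\sigma^2_e = 1$ —
each QTL then explains roughly 10% of the phenotypic variance, a clearly
detectable but not trivial signal at $n = 1{,}000$. Everything is
bit-reproducible given `seed`.

What passing tests on these data do **not** show: robustness to genotyping
artefacts beyond random missingness, to assembly/map errors, to multi-breed
structure, or to the much weaker per-QTL signals expected for real
low-heritability reproduction traits; the simulator makes no attempt to
reproduce any published dataset's results.

## Quality control

Markers are kept iff MAF $> 0.01$, call frequency $> 0.9$, mean GenCall
$> 0.60$, Hardy–Weinberg $\chi^2_1$ $p > 10^{-7}$ and a map position exists
(all inequalities strict); animals with call rate $< 0.8$ are excluded.
Animals are filtered first and marker statistics recomputed on the kept
animals, matching common chip-QC practice. The HWE test is the 1-df
goodness-of-fit chi-square with the allele frequency estimated from the
sample (monomorphic markers pass by convention). Missing genotypes are
imputed naively by the marker's rounded mean — LD-aware imputation is out of
scope, and at chip-scale call rates the rounded mean changes each marker's
allele frequency by at most $0.5k/(2n)$ for $k$ missing calls.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 11)        # 1,000 individuals, 2,000 markers, 4 QTL
d <- simulate_dataset(cfg)

scan <- lmm_gwas(d$phenotypes$y_c, d$geno, d$A, d$phenotypes$weight, d$map)
print(scan)

bm <- bayes_mixture(d$phenotypes$y_c, d$geno, pedigree = d$pedigree,
                    weights = d$phenotypes$weight, map = d$map,
                    chain = gibbs_config(5200, 2000, 2, seed = 1))
regions <- qtl_regions(bm, window_bp = 1e6)
print(regions)
```

## Problem sizes used by the validation suite

The test suite and the acceptance script size their experiments as follows,
as the package's own validation design: calibration of the null scan pools
five independent no-QTL simulations of 450 individuals and 2,500 markers
(12,500 tests); the region-recovery experiment runs 20 replicates of the
standard study conditions with the scaled-down chain; sampler-level
distributional checks (prior-only Kolmogorov–Smirnov, flat-likelihood
inclusion rates) use long thinned chains on small fixtures.

## Known limitations

* Exact REML is $O(n^3)$ in the number of phenotyped animals via one
  eigendecomposition — fine at desk scale, not for national evaluations.
* The mixture model fixes the variance ratio at 100 and uses exactly two
  components; no model-averaging over window sizes is attempted, and the
  cross-size "narrowest informative window" choice is left to the analyst.
* Naive mean imputation ignores LD; heavily missing data should be imputed
  externally before analysis.
* The region-variance *proportion* depends on the denominator convention
  (documented above); comparisons across studies should check which total is
  used.
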
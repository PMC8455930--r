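---
title: "Multi-trait genomic risk scores: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait genomic risk scores: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtgrs)
```

## The problem

A genomic risk score (GRS) summarises a person's inherited liability to a
disease as a weighted sum of risk-allele counts,
$\mathrm{GRS}_j = \sum_i X_{ji}\,\hat b_i$, with weights taken from a
genome-wide association study (GWAS). For a complex disease such as type 2
diabetes the marginal effects $\hat b_i$ are individually tiny and noisily
estimated, so the single-trait (ST) score explains only a small fraction of
risk. Many complex traits are *genetically correlated* with the disease of
interest — body mass index, blood pressure, medication burden — and their
GWAS are often far better powered. `mtgrs` implements the multi-trait
(MT) strategy: re-weight each marker's effects across $k$ correlated
traits with a selection index so that the combined effect is a better
predictor of the focal trait's true marker effect, then score and evaluate
exactly as for a single-trait GRS.

## The selection index

Write $\hat{\mathbf b}_i = (\hat b_{1i},\dots,\hat b_{ki})'$ for the
estimated effects of marker $i$ on the focal trait (first) and the $k-1$
information traits. The index weight vector solves
$\mathbf w = \mathbf V^{-1}\mathbf C$ where $\mathbf V$ is the
variance–covariance matrix of estimated effects and $\mathbf C$ the vector
of covariances between each trait's estimates and the focal trait's *true*
effects. Under an infinitesimal model in which a genome behaves like $M$
independently segregating segments,

$$\mathrm{var}(\hat b_k) = \frac{h_k^2}{M} + \frac{1}{N_k},
\qquad
\mathrm{cov}(\hat b_k, \hat b_l) = \frac{r_{g,kl}\,h_k h_l}{M},$$

with $h_k^2$ the heritability, $N_k$ the GWAS sample size and $r_g$ the
genetic correlation. The adjusted effect of marker $i$ is
$\hat b^{MT}_i = \mathbf w'\hat{\mathbf b}_i$ and the MT-GRS is its
allele-count-weighted sum. Every ingredient ($h^2$, $r_g$, $N$) is
estimable from summary statistics alone, which is what makes the approach
practical: individual-level data are needed only for scoring.

`index_weights()` implements the solve with two numerical safeguards
motivated by the fact that $h^2$ and $r_g$ arrive as noisy estimates:

* off-diagonal $r_g$ entries are clamped to $[-0.999, 0.999]$, and
* the $r_g$ matrix is projected to the nearest positive semi-definite
  correlation matrix (eigenvalues clipped at $10^{-6}$, diagonal rescaled
  to one).

The projection matters in practice. Pairwise LD-score estimates of $r_g$
need not be jointly consistent; with seven information traits a focal row
of over-estimated correlations alongside weakly correlated information
traits routinely produces an indefinite matrix, and solving against the
raw estimates can flip the focal trait's weight negative — the MT score
then *subtracts* the focal GWAS signal. A condition-number guard
($\kappa > 10^{12}$) still rejects genuinely degenerate systems, naming
the worst trait pair. $M$ defaults to 60,000, the conventional effective
number of chromosomal segments for a European-ancestry genotyping panel;
for simulated genomes we set it to the number of LD blocks.

## Estimating the genetic parameters

**LD scores.** For marker $i$,
$l_i = \sum_k \tilde r^2_{ik}$ over a window of `window` markers centred
on $i$ (default 5,000, i.e. 2,500 to each side), where
$\tilde r^2 = r^2 - (1 - r^2)/(N - 2)$ corrects the upward bias of the
sample squared correlation. The self term contributes exactly 1 and
windows never span chromosomes. On synthetic genomes whose LD is confined
to short blocks we use a window of 101 markers: beyond the block the true
$r^2$ is zero and additional window terms only add noise (each with mean
$\approx 0$ after the bias adjustment) and compute time.

**Heritability and genetic correlation.** With association z-scores
$z_i = \hat b_i / \mathrm{SE}(\hat b_i)$, LD-score regression estimates
$h^2$ as the slope of $z_i^2$ on $Z_i = n_{\mathrm{eff}}\, l_i / m$, and
$r_g$ from the slope of $z_{1i} z_{2i}$ on $\sqrt{n_1 n_2}\, l_i / m$
divided by $\sqrt{h_1^2 h_2^2}$. Three intercept treatments are provided:

* `intercept = "none"` (the default): the plain no-intercept
  least-squares slope $(\mathbf Z'\mathbf Z)^{-1}\mathbf Z'\mathbf y$.
  This is the literal form of the estimating equations, but because a null
  chi-square statistic has expectation 1 ($E[z^2] = 1 + Z h^2$), the
  no-intercept slope absorbs that unit and is biased upward — visibly so
  at simulation scale, where $Z$ is of order one.
* `intercept = "free"`: estimates the intercept, removing the bias at the
  cost of considerable variance when the spread of $l$ is modest.
* `intercept = "fixed"`: constrains the intercept to its known null value
  (1 for squared z-scores; for z-score products, the phenotypic
  correlation scaled by the sample-overlap fraction) and regresses the
  excess through the origin. In the absence of confounding this is the
  lowest-variance consistent estimator, and it is what
  `cross_validate()` uses by default.

At the package's reference simulation scale ($n = 2{,}000$ samples,
$m = 5{,}000$ markers, $h^2 = 0.5$, $r_g = 0.6$) the fixed-intercept
estimates recover the truth to within a few hundredths on average, with a
per-replicate standard deviation of roughly 0.065 for $h^2$ and 0.07 for
$r_g$; the free-intercept variants are unbiased but three to four times
noisier, and the literal no-intercept form overshoots by design. All three
behaviours are exercised in the test suite.

**Effective sample size.** $n_{\mathrm{eff}}$ is the median over markers
of $1 / (2\,\mathrm{af}(1-\mathrm{af})\,\mathrm{SE}^2)$: for a variance-1
outcome the sampling variance of a marginal allele-count coefficient is
$\approx 1/(n \cdot 2\,\mathrm{af}(1-\mathrm{af}))$, so each marker gives
an estimate of $n$ and the median is robust. The formula assumes a
variance-1 outcome; applied to log-odds standard errors it returns
$n\,K(1-K)$ instead of $n$, silently rescaling the heritability. For
binary traits analysed internally, `cross_validate()` therefore uses the
actual GWAS sample count, which keeps the focal $h^2$ on the standardized
observed scale — the scale on which the usual liability transform
$h^2_{liab} = h^2_{obs}\,K(1-K)\,/\,\varphi(\Phi^{-1}(1-K))^2$
(`observed_to_liability()`) applies.

## Association scans

`marginal_gwas()` fits `y ~ allele count + covariates` per marker.
Linear scans use Frisch–Waugh residualisation so the whole panel is one
set of matrix products; logistic scans run IRLS per marker (deviance
tolerance $10^{-8}$, 50 iterations), report Wald statistics, and flag
monomorphic or non-converged markers so downstream stages drop them.
Samples with a missing call are excluded marker by marker. Quantitative
traits are covariate-adjusted and inverse-rank normalized
(Blom offset, $\Phi^{-1}((r - 3/8)/(n + 1/4))$, average ranks for ties)
before the scan; binary outcomes are analysed as 0/1 with the covariates
in the model, never rank-normalized. External summary statistics reported
as odds ratios are converted by $\hat b = \log \mathrm{OR}$,
$\mathrm{SE} = |\hat b| / \Phi^{-1}(1 - p/2)$; `harmonize()` aligns
effect alleles to the scoring panel (negating effects and complementing
frequencies for swapped pairs, dropping incompatible pairs). Strand
ambiguity (A/T, C/G pairs) is not specially handled — a real limitation
for external data on unknown strand conventions.

## Marker selection and scoring

`ld_prune()` is clumping-style: markers are visited in ascending
focal-trait P-value (ties broken by position) and kept only if their
$\tilde r^2$ with every kept marker inside the window stays below the
ceiling. P-priority was chosen because the retained set is subsequently
P-thresholded, and it makes the output deterministic. `p_threshold()` is
a strict cut ($p <$ threshold). The marker subset is selected **once**
from the focal statistics and reused for all traits, so ST and MT scores
are computed on identical markers; the conventional threshold grids are
available via `default_p_grid()`. Missing genotypes are imputed at
scoring time to twice the training allele frequency.

## Evaluation

`nagelkerke_r2()` measures the *incremental* variance explained:
$$R^2 = \frac{1 - e^{-\mathrm{LR}/n}}{1 - e^{2 L_0 / n}},$$
where $\mathrm{LR}$ compares the logistic model with covariates plus
score against covariates alone and $L_0$ is the reduced model's
log-likelihood (the denominator is the attainable maximum of the
Cox–Snell numerator, so a useless score gives exactly 0 and the measure
is invariant to affine transforms of the score). `percentile_stratify()`
ranks scores into 100 equal-occupancy bins (stable order for ties),
reports per-bin prevalence, and fits each bin's odds ratio against the
reference percentile (default the 50th) in a *separate* logistic model
with covariates — separate fits so that an empty bin invalidates only its
own estimate. The fold-level spread of $R^2$ is summarised as the
standard error of the mean with a $k-1$ denominator.

`cross_validate()` ties the stages together: fold assignment
(`split_folds()`, sizes differing by at most one), per-trait GWAS on the
training folds, LD scores and genetic parameters on the training data,
index weights, and scoring plus evaluation on the held-out fold, for every
scenario and grid cell. `focal_frac < 1` trains the focal GWAS on a
subset of the training folds, emulating the common situation where the
disease GWAS is case-limited while information-trait GWAS draw on the
full cohort.

## What the generator simulates — and what it does not

`simulate_genotypes()` draws each marker's minor allele frequency
uniformly from `maf_range` (default 0.05–0.5) and generates two haplotype
layers per block from a latent Gaussian AR(1) process (parameter
`within_block_rho`, default 0.9; block size default 20 markers),
thresholded at the frequency quantile and summed, giving Hardy–Weinberg
counts whose correlation decays geometrically within a block and is zero
across blocks. `simulate_phenotypes()` samples `n_causal` markers
(default $m/10$) and draws their per-trait effects jointly with
covariance $r_{g,kl}\,h_k h_l / n_\mathrm{causal}$ on standardized
genotypes, adds independent residuals to unit total variance, shifts by
sex (Bernoulli 1/2, effect 0.25) and age (57.5 ± 8 years, effect 0.3 per
SD), and thresholds binary traits at the theoretical $1-K$ liability
quantile (default prevalence 0.056, a typical adult type-2-diabetes case
fraction), so the realized case count carries ordinary binomial noise.
All randomness flows from one seed through `derive_seed()`, a documented
stream-split, so genotypes, phenotypes and fold assignment are
independently reproducible. Missingness defaults to 0 — the generator
emulates a post-QC hard-call matrix — and is injected only on request.

The generator deliberately does **not** simulate realistic human LD maps,
population structure, relatedness, imputation dosages, or any coupling
between allele frequency and effect size (the standardized-genotype
effect model is a choice, equivalent to rarer alleles having larger
per-allele effects). Passing tests therefore demonstrate that the
estimators and the scoring pipeline behave correctly under the stated
generative model; they do not certify performance on real cohort data,
where confounding, stratification and cross-ancestry LD differences are
the dominant hazards.

## Problem sizes and study-like conditions

Two reference experiments are used throughout the tests and the
acceptance script, at sizes chosen to finish on a single CPU while
leaving the estimators enough data to be meaningfully tested:

* **Parameter recovery** — bivariate quantitative simulation,
  $n = 2{,}000$, $m = 5{,}000$, $h^2 = 0.5$ each, $r_g = 0.6$, LD-score
  window 101, averaged over replicate seeds.
* **Study-like comparison** — $n = 4{,}000$, $m = 1{,}500$ in 75 blocks,
  a binary focal trait with liability $h^2 = 0.3$ and prevalence 0.056
  (observed-scale $h^2 \approx 0.07$), seven quantitative information
  traits with $h^2 = 0.5$ and $r_g$ to the focal trait between 0.3 and
  0.6 (0.2 among themselves), two-fold cross-validation, LD ceiling 0.9,
  thresholds $\{0.1, 0.5, 0.99\}$, $M = 75$. Under these conditions the
  S1 multi-trait score beats the single-trait score in every replicate
  we run, with a mean relative gain of roughly 25–30% — the qualitative
  behaviour the method was designed for, strongest when the information
  traits are well powered relative to the focal GWAS.

```{r, eval = FALSE}
# the study-like comparison, one seed
cfg <- sim_config(4000, 1500,
                  h2 = c(0.3, rep(0.5, 7)),
                  rg = {
                    r <- diag(8)
                    r[1, 2:8] <- r[2:8, 1] <- c(0.6, 0.55, 0.5, 0.45,
                                                0.4, 0.35, 0.3)
                    o <- r[2:8, 2:8]; o[o == 0] <- 0.2; r[2:8, 2:8] <- o
                    r
                  },
                  trait_types = c("binary", rep("quantitative", 7)),
                  prevalence = 0.056, seed = 1)
G  <- simulate_genotypes(cfg)
ph <- simulate_phenotypes(G, cfg)
cv <- cross_validate(G, ph, traits = paste0("trait", 1:8),
                     trait_types = cfg$trait_types, scenarios = "S1",
                     r2_grid = 0.9, p_grid = c(0.1, 0.5, 0.99),
                     k_folds = 2, M = 75, window_ld = 101,
                     window_prune = 101, seed = 1)
cv$summary
```

## Scenarios

Four weighting scenarios are supported by `build_scenario()`, differing
in which summary statistics enter the index: S1 uses the internally
estimated focal statistics plus the information traits; S2 swaps the
focal statistics for one external study of the same disease; S3 uses one
external study plus the information traits plus the internal focal
statistics; S4 augments S1 with every available external study. External
files are read with `read_sumstats()` (column aliases, OR conversion)
and must be harmonized to the scoring panel first. For S2 the
heritability entering $\mathbf C$ is the one estimated from the
statistics actually being weighted, not the internal focal estimate.

## Known limitations

* The liability-scale conversion assumes a population sample; it is not
  valid for case-control ascertained data.
* No LD-score regression intercept is reported as a confounding
  diagnostic; the intercept options here are estimator variants, not a
  stratification test.
* Logistic and linear effects are combined by the index on their native
  scales (log-odds and standardized-trait units respectively), as is
  conventional for this class of method; the weights absorb scale
  differences only through the $h^2$ and $N$ inputs.
* `harmonize()` matches by marker id with no strand-ambiguity handling.
* Windows are marker-count based, not physical distance.
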
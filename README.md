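# mtgrs — multi-trait genomic risk scores

`mtgrs` builds and evaluates genome-wide risk scores for a focal disease
by borrowing strength from genetically correlated traits. A single-trait
score (ST-GRS) is the familiar weighted allele count,

    ST-GRS_j = Σ_i X_ji · b̂_i ,

with marginal GWAS effects b̂ selected by LD pruning and P-value
thresholding. The multi-trait score (MT-GRS) replaces each marker's focal
effect with a selection-index combination across k traits,
b̂_MT = w' b̂, where the weights solve **w = V⁻¹C** with

    var(b̂_k)      = h²_k / M + 1 / N_k
    cov(b̂_k, b̂_l) = r_g,kl · h_k · h_l / M

— h² the heritability, N the GWAS sample size, r_g the genetic
correlation and M the effective number of independent chromosomal
segments (60,000 by default). All genetic parameters are estimated from
summary statistics alone via bias-adjusted LD scores
(r̃² = r² − (1 − r²)/(N − 2)) and LD-score regression; individual-level
genotypes are needed only for scoring. Score accuracy is measured as the
incremental Nagelkerke R² of the score over a covariate-only logistic
model, with percentile risk stratification (per-bin prevalence and odds
ratios against the 50th percentile) for visualising the risk gradient.

The package is aimed at statistical geneticists who want a
self-contained, testable implementation of the whole chain — synthetic
multi-trait cohorts, QC, marginal GWAS, LD-score regression, index
weighting, clumping-and-thresholding, scoring, cross-validated
evaluation — plus PLINK1 bed/bim/fam and delimited-text readers/writers
and a thin command-line front end (`inst/cli/mtgrs.R`).

## Worked example

Simulate a cohort with a binary focal trait (prevalence 0.056, liability
h² = 0.3 → observed scale ≈ 0.07) and two correlated quantitative
information traits, then compare ST and multi-trait (S1) scores under
two-fold cross-validation:

```r
library(mtgrs)

cfg <- sim_config(n_individuals = 2000, n_markers = 800,
                  h2 = c(0.3, 0.5, 0.5),
                  rg = matrix(c(1,   0.6, 0.4,
                                0.6, 1,   0.2,
                                0.4, 0.2, 1), 3),
                  trait_types = c("binary", "quantitative", "quantitative"),
                  prevalence = 0.056, seed = 42)
G  <- simulate_genotypes(cfg)
ph <- simulate_phenotypes(G, cfg)

cv <- cross_validate(G, ph, traits = c("trait1", "trait2", "trait3"),
                     trait_types = cfg$trait_types, scenarios = "S1",
                     r2_grid = 0.9, p_grid = c(0.1, 0.5, 0.99),
                     k_folds = 2, M = 40, window_ld = 101,
                     window_prune = 101, seed = 42)
print(cv$summary, digits = 3)
#>   scenario r2_max p_max mean_r2     sem n_folds
#> 1       S1    0.9  0.10  0.0213 0.00497       2
#> 2       ST    0.9  0.10  0.0204 0.00558       2
#> 3       S1    0.9  0.50  0.0309 0.00375       2
#> 4       ST    0.9  0.50  0.0290 0.00217       2
#> 5       S1    0.9  0.99  0.0317 0.00565       2
#> 6       ST    0.9  0.99  0.0291 0.00274       2
```

The multi-trait score explains more case/control variance than the
single-trait score at every threshold (here ~9% more at the best
setting). The per-fold genetic parameters behind the weights:

```r
p1 <- cv$params[[1]]
round(p1$h2, 3)
#> trait1 trait2 trait3
#>  0.068  0.421  0.512
round(p1$rg, 2)
#>        trait1 trait2 trait3
#> trait1   1.00   0.48   0.36
#> trait2   0.48   1.00   0.09
#> trait3   0.36   0.09   1.00

index_weights(pmax(p1$h2, 1e-6), p1$rg, N = p1$n_eff, M = 40)
#> index_weights (k = 3, M = 40)
#> [1] 0.5427 0.0753 0.0499
```

The focal trait's observed-scale heritability (0.068 in fold 1, true
value ≈ 0.07 for liability h² = 0.3 at K = 0.056) and the estimated
genetic correlations reproduce the simulation settings up to sampling
noise, and the information trait with the larger r_g to the focal trait
receives the larger weight. `observed_to_liability()` converts observed-
scale estimates back to the liability scale.

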
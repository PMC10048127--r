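# dyadclust

Model-based clustering of paired binary outcomes with high-dimensional
compositional covariates — built for mother–child dyads where both members'
caries status (1 = caries, 0 = none) and salivary microbiome profiles are
observed, and where latent subgroups of families (typical, high–low,
low–high caries patterns) differ in *which* taxa relate to disease.

## The method

Within each cluster, a logistic random-intercept model ties the two members
of dyad *i* together:

    y_im | b_i ~ Bernoulli( logit^-1( beta0 + x_im' beta + b_i ) ),
    b_i ~ N(0, sigma_b^2)

with the marginal likelihood evaluated by adaptive Gauss–Hermite quadrature
and the slopes estimated under an L1 (LASSO) penalty on the standardized
scale, `lambda` chosen per cluster per iteration by AIC. The selected
coefficients are re-estimated without penalty to remove shrinkage bias, and
the refit predicts each dyad's pair of caries probabilities
(p_mother, p_child). Euclidean k-means on these probability pairs — each
dyad treated as a two-point trajectory — reassigns dyads to clusters, and
the two stages alternate until membership stops changing. `exp(beta_j)` is
the odds ratio of caries per one-unit increase in relative abundance of
taxon *j*, holding the rest fixed and ignoring the random intercept.

The package also ships the standard periphery: OTU-table filtering
(prevalence ≥ 20% at count ≥ 4; lowest-IQR removal), dyad assembly from
feature + metadata tables, a synthetic dyad generator with known truth,
per-cluster caries summary tables, Benjamini–Hochberg-controlled
cross-cluster screens, and Shannon / Bray–Curtis / PCoA / PERMANOVA
diversity statistics.

## Worked example

Simulate 180 dyads from three planted clusters (low–low, high–low, low–high
caries patterns driven by mother/child-contrasted taxa), cluster them, and
summarize:

```r
library(dyadclust)

sim <- generate_dyads(synthetic_config("strong-separation", seed = 1))
res <- run_alternating(sim$data, k = 3, seed = 1)
res
#> Alternating GLMM-LASSO clustering: k = 3, 180 dyads
#>   1 iteration(s), converged: TRUE
#>   cluster sizes:  60/60/60

summarize_clusters(dyad_outcomes(sim$data, res))
#>   cluster n_dyads mother_pct child_pct both_pct neither_pct individuals_pct
#> 1       1      60      91.67      6.67     6.67        8.33           49.17
#> 2       2      60      21.67     85.00    18.33       11.67           53.33
#> 3       3      60      11.67     15.00     1.67       75.00           13.33
#> 4 Overall     180      41.67     35.56     8.89       31.67           38.61

adjusted_rand_index(res$labels$cluster, sim$truth$labels$cluster)
#> [1] 1
```

Cluster 1 is the recovered high–low group (91.67% of mothers affected,
6.67% of children), cluster 2 the low–high group, cluster 3 the
mostly-healthy group; the partition matches the generating labels exactly
(adjusted Rand index 1). Per-cluster coefficients read as odds ratios:

```r
tidy(res$fits[[2]])
#> # A tibble: 3 × 4
#>   term        estimate odds_ratio std_error
#>   <chr>          <dbl>      <dbl>     <dbl>
#> 1 (Intercept)   -0.688      0.502        NA
#> 2 otu007         2.30      10.0         NA
#> 3 otu009         3.83      46.2         NA

round_half_up(odds_ratio_from_coef(0.417), 2)   # a logit coefficient of 0.417
#> [1] 1.52
```

`autoplot(res)` draws the (p_mother, p_child) probability pairs colored by
cluster. For file-based workflows, `run_pipeline()` (or the thin CLI wrapper
in `inst/cli/dyadclust.R`) reads a feature table and metadata CSV, applies
the filters, clusters, and writes labels, per-cluster coefficient JSON, the
caries summary, diversity statistics, an iteration log, and the full
configuration (with seed and content hash) to an output directory.

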
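---
title: "Alternating GLMM-LASSO clustering of mother-child dyads: model and methods"
author: "dyadclust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alternating GLMM-LASSO clustering of mother-child dyads: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadclust)
```

## The problem

Early childhood caries co-occurs within families: a mother's oral microbiome
and caries status are tied to her child's, yet mother-child pairs are not all
alike — some dyads share poor oral health, in others a high-risk mother has a
caries-free child, or the reverse. `dyadclust` implements a model-based
clustering method for exactly this situation: paired binary outcomes
(caries / no caries for each member of a dyad), high-dimensional compositional
covariates (relative abundances of oral taxa), and latent subpopulations that
differ both in their outcome pattern and in *which* taxa drive the outcome.

## The model

Within a cluster, each dyad $i$ contributes two Bernoulli observations (mother
and child) sharing a dyad-level random intercept:

$$
y_{im} \mid b_i \sim \mathrm{Bernoulli}\!\left(\mathrm{logit}^{-1}(\beta_0 +
x_{im}^\top \beta + b_i)\right), \qquad b_i \sim N(0, \sigma_b^2),
$$

with the logit link throughout. The marginal log-likelihood integrates $b_i$
out:

$$
\ell(\beta_0, \beta, \sigma_b) = \sum_i \log \int
\prod_{m \in \{\text{mother},\, \text{child}\}}
\pi_{im}(b)^{y_{im}} (1 - \pi_{im}(b))^{1 - y_{im}}\,
\phi(b; 0, \sigma_b^2)\, db .
$$

The integral has no closed form; `dyadclust` evaluates it by adaptive
Gauss-Hermite quadrature: for each dyad the integrand's mode and curvature
are found by a few Newton steps, the Gauss-Hermite grid (15 nodes by default)
is recentered and rescaled there, and the weighted sum is accumulated in log
space. With two observations per group this is accurate to well below
$10^{-6}$ per dyad for $\sigma_b \lesssim 1.5$, the regime relevant here; the
test suite checks the quadrature against a 2001-point brute-force trapezoid
integral and against a 51-node evaluation. When $\sigma_b = 0$ the likelihood
collapses to the ordinary Bernoulli sum and is evaluated exactly. The kernel
is implemented in C++ (`src/agq.cpp`) with a pure-R reference implementation
cross-checked in the tests.

### Penalized estimation

Because the covariate dimension (184 taxa after filtering, at the scale the
method targets) exceeds what 100-odd dyads can support, slopes are estimated
under an L1 penalty:

$$
\max_{\beta_0, \beta, \sigma_b}\;
\ell(\beta_0, \beta, \sigma_b) - \lambda \sum_j |\beta_j^{(\mathrm{std})}|,
$$

where the penalty acts on slopes for internally standardized covariates (so
the penalty is scale-equivariant; fitted probabilities are identical whether
the caller pre-scales or not), and the intercept and variance component are
unpenalized. Optimization alternates monotone accelerated proximal-gradient
steps on $(\beta_0, \beta)$ — soft-thresholding produces exact zeros — with
bounded one-dimensional optimization of $\log \sigma_b$, stopping when the
parameter change falls below `tol` (default $10^{-6}$). The penalized
objective is non-increasing across iterations by construction (a backtracking
line search accepts only descent steps), and the fit records its objective
trace so the property is assertable. Fits warm-start at the
intercept-plus-variance null model, which also anchors $\lambda_{\max}$ — the
supremum norm of the null-model score with respect to the standardized
slopes — at which, and above which, every slope is exactly zero by the
soft-threshold stationarity condition.

### Penalty selection, re-estimation, prediction

For each cluster at each outer iteration, $\lambda$ is chosen by AIC over a
fresh grid of 25 log-spaced values from $\lambda_{\max}$ down to
$10^{-3}\lambda_{\max}$ (fresh because cluster composition changes between
iterations), warm-starting each fit from its larger-$\lambda$ neighbour.
AIC is $-2\ell + 2\,\mathrm{df}$ with $\mathrm{df}$ = number of nonzero
slopes + 1 (intercept) + 1 if $\sigma_b$ is above its boundary tolerance
($10^{-4}$; smaller values are reported as exactly 0). AIC is computed from
the penalized fit; ties — AICs within $10^{-8}$ — resolve to the largest
(sparsest) $\lambda$.

The selected support is then re-estimated *without* penalty (L-BFGS-B on the
same marginal likelihood), removing LASSO shrinkage bias; standard errors
come from the inverse numerical Hessian at the optimum and match
`lme4::glmer(nAGQ = 15)` to four decimals in the test fixtures. Each dyad's
pair of caries probabilities is predicted from the refit. The default is the
marginal prediction $\hat\pi = \mathrm{logit}^{-1}(\hat\beta_0 + x^\top
\hat\beta)$ with the random intercept set to zero, consistent with
interpreting coefficients while ignoring the random intercepts; a conditional
mode adding the posterior mode $\hat b_i$ given the dyad's outcomes is
available (`probability_mode = "conditional"`). The published description
does not say whether the probabilities fed to the clustering stage included
the estimated random intercepts; marginal was chosen as the default because
it makes the probability pair a function of the covariates alone, so dyads
are grouped by their modeled risk profile rather than partly by their
observed outcomes.

### The alternating loop

1. **Initialize**: k-means on one vector per dyad — the standardized mother
   and child covariate rows, concatenated (averaging available) — treating
   each dyad as one observation; the outcome is not used.
2. **Model stage**: per cluster, select $\lambda$ by AIC, fit, re-estimate on
   the support, predict each member's probability.
3. **Clustering stage**: Euclidean k-means (Lloyd's algorithm) on the
   $(\hat p_{\text{mother}}, \hat p_{\text{child}})$ pairs — each dyad's
   two-point response trajectory. Assignment ties go to the lowest cluster
   index; an emptied cluster is reseeded at the point farthest from its
   assigned center; the best of 10 seeded restarts by inertia is kept.
4. Repeat 2-3 until membership stops changing between consecutive
   iterations.

Because a fresh k-means permutes cluster ids arbitrarily, each new partition
is first greedily relabeled to maximally overlap the previous one;
"membership stopped changing" is a statement about the partition, not the
arbitrary ids. Label vectors are hashed across iterations: if a previously
visited partition recurs, the loop is in a cycle, stops with
`converged = FALSE`, and returns the visited state with the smallest AIC sum.
Clusters smaller than `min_cluster_dyads` (default 3), clusters with constant
outcomes, and clusters whose fit fails for any reason are handled by a
separation-safe fallback — an intercept-only model at the clipped rate
$(r + 0.5)/(n + 1)$ with $\sigma_b = 0$, flagged in the result — rather than
aborting the run. Perfect separation in a refit is detected as a
standardized slope exceeding 15 in magnitude and handled the same way.

The number of clusters $k$ is fixed by the user (default 3); no automatic
selection is attempted. All randomness flows from one master seed: the
initialization uses the seed itself, and the trajectory k-means at outer
iteration $i$ uses `seed + i`, so identical data, configuration and seed
reproduce bit-identical labels.

## Feature filtering

Raw OTU tables are filtered in two stages before modeling, mirroring common
microbiome practice:

* **Prevalence/abundance**: keep a feature only if its count reaches
  `min_count` (default 4) in at least `ceiling(min_prevalence * n)` samples
  (default 20%). The threshold is interpreted per sample joined with
  prevalence — the conventional prevalence filter — because the alternative
  (a total-count threshold) cannot be distinguished from the published
  feature counts alone.
* **Spread**: drop the `drop_fraction` (default 10%) of features with the
  smallest spread, interquartile range by default (variance available), ties
  resolved toward earlier-listed features. Both the fraction and the
  statistic are configurable because the source pipeline states neither.

Covariates default to relative abundances (each sample row divided by its
total), so a coefficient reads as the change in log-odds per unit relative
abundance; raw counts and `log(p + 1e-6)` transforms are available via
`covariate_scale`.

Dyads missing a member are dropped with a warning (or an error under
`strict = TRUE`) — the paired likelihood needs complete pairs, and imputing a
missing family member's microbiome would manufacture data.

## The synthetic generator

`generate_dyads()` draws from the model itself: cluster labels with known
sizes; latent mother covariate vectors around cluster-specific means; child
vectors as $\rho$-correlated copies ($z_c = \mu_c + \rho(z_m - \mu_m) +
\sqrt{1-\rho^2}\,\varepsilon$, so $\rho = 1$ duplicates the mother); an
optional compositional transform (exponentiate with feature-specific
log-means, log-scale SD 2, then row-normalize — the heavy-tailed skew of
real OTU tables); a shared random intercept; and Bernoulli outcomes from the
cluster's sparse logistic model. Generation is deterministic given the
configuration seed, and the generating labels, coefficients and intercepts
are returned for recovery tests.

Two presets define the package's study conditions:

* **`strong-separation`** (recovery benchmark): 3 balanced clusters of 60
  dyads, 9 gaussian covariates, disjoint 3-feature supports with slopes
  $\pm 3$, $\sigma_b = 0.5$, within-dyad covariate correlation 0.25. The
  unpinned geometry was designed so the three clusters sit at the corners of
  probability space — low-low near (0.10, 0.10), high-low near (0.90, 0.10),
  low-high near (0.10, 0.90) — with the off-diagonal patterns produced by
  mother-versus-child *role contrasts* in covariate means (taxa enriched in
  mothers and depleted in children, or vice versa) under a shared
  coefficient vector, the same mechanism that can make a low-risk mother's
  child high-risk in real dyads. The corner placement is deliberate margin
  engineering: at 60 dyads per cluster an AIC-selected model occasionally
  admits a handful of spurious features, and their unpenalized refit spreads
  the cluster's fitted probabilities by up to ~0.2; pairwise center
  distances of at least 0.8 keep the trajectory k-means stable against that
  spread. At freeze, full runs over twelve consecutive seeds recovered the
  generating partition with adjusted Rand index between 0.90 and 1.00, all
  with three non-empty clusters.
* **`paper-scale`** (dimension exercise): cluster sizes 122/39/14, 184
  compositional features, supports of sizes 1/14/4, $\sigma_b = 1$ — the
  dimensions of the motivating caries study. Its 14-dyad third cluster makes
  reliable recovery impossible by design; the preset exists to exercise the
  code path at realistic scale, not to benchmark accuracy.

What the generator does *not* emulate: phylogenetic correlation among taxa,
sequencing depth variation and zero inflation beyond what the log-normal
transform produces, and covariate measurement error. Passing recovery tests
therefore show that the algorithm recovers structure *of the kind it
models*; they do not certify performance on real tables whose noise
structure differs.

## Post-clustering statistics

`summarize_clusters()` tabulates per-cluster counts and percentages of dyads
with both members affected, mother affected, child affected, neither, and
the pooled share of affected individuals; `pool_overall()` always pools
integer counts and divides by totals, never averages percentages.
Percentages print with round-half-up at 2 decimals, matching the published
tables' convention (base R's banker's rounding would disagree on exact
halves). Coefficients are reported as odds ratios via `exp(beta)`.

Cross-cluster screens use a chi-square test of independence for categorical
factors — switching to a seeded Monte-Carlo permutation p-value
$(1 + \#\{\text{extreme}\})/(1 + B)$ when any expected cell drops below 5 —
and Kruskal-Wallis for abundances; the source work does not name its tests,
and these are the field's standard defaults for those data types. All
p-values from a screen are Benjamini-Hochberg adjusted, and displayed in the
buckets `<0.05`, `<0.01`, `<0.001`.

## Ecology metrics

Shannon diversity uses the natural log by default (base configurable);
Bray-Curtis is $\sum|x_i - y_i| / \sum(x_i + y_i)$; both delegate to
**vegan**. PCoA is classical MDS (`cmdscale`): negative eigenvalues — which
Bray-Curtis produces — are reported but excluded from the percent-explained
denominator, and no Lingoes/Cailliez correction is applied since the source
analysis states none. PERMANOVA delegates to `vegan::adonis2` with seeded
permutations and the add-one p-value estimator; the test suite verifies the
pseudo-F against a hand-computed Gower-centered evaluation and the test's
exactness under the null (rejection rate 0.05 within Monte-Carlo error).
For alpha-diversity group comparisons the paired-versus-unpaired choice of
t-test is exposed to the caller rather than silently defaulted, because the
source analysis does not state which was used for mother-child contrasts.

## Numerical choices, in one place

* Quadrature: 15 adaptive Gauss-Hermite nodes (configurable); exact
  Bernoulli sum at $\sigma_b = 0$; accuracy verified against brute force.
* Proximal gradient: monotone FISTA with backtracking; step growth 1.5;
  convergence on parameter change $< 10^{-6}$ or 500 iterations.
* $\sigma_b$: optimized on the log scale within $[10^{-6}, 8]$; its profile
  can be numerically flat near the optimum, so convergence also accepts a
  $\sigma_b$ step whose objective improvement is below $10^{-8}$; profiles
  flat down to the boundary collapse to exactly 0; values below $10^{-4}$
  report as 0.
* Degenerate clusters: intercept-only fallback at rate $(r+0.5)/(n+1)$,
  flagged.
* K-means: ties to the lowest index, empty clusters reseeded at the
  farthest point, 10 restarts, best inertia.
* Probabilities clipped to $[10^{-12}, 1 - 10^{-12}]$.

## Problem sizes used by the checks

The bundled verification suite runs, among smaller fixtures: the
strong-separation benchmark (180 dyads, 9 features) over 20 seeds; 50
replicates of a 500-dyad, 20-feature, 3-true-slope recovery design with
$\sigma_b = 1$ (pooled $\pm 2$ SE coverage, nominal ~95%); and 500-simulation
null calibrations of PERMANOVA (20 samples, 199 permutations) and the
categorical cluster screen. These sizes were chosen so each check estimates
its property with useful precision on a single CPU.

## Known limitations

* Only the two-member (dyad) case of the trajectory k-means is implemented;
  for two-point trajectories it reduces to plain Euclidean k-means, and no
  trajectory-specific normalization is applied.
* No random slopes, no nesting beyond the dyad, logit link only, no
  Gaussian-outcome mode, and no automatic choice of $k$.
* AIC-guided selection is permissive at small cluster sizes; clusters of a
  few dozen dyads can admit spurious features whose refit widens the
  probability cloud. The algorithm tolerates this (see the fixture design
  above) but per-cluster supports from small clusters should be read with
  corresponding skepticism.
* The published per-subject data behind the motivating study are not
  available in tabular form, so the package's checks rest on the published
  tables' internal arithmetic and on synthetic data with known truth.
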
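Package: dyadclust
Title: Alternating GLMM-LASSO Clustering of Paired Binary Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Model-based clustering of correlated binary outcomes observed on
    paired subjects (mother-child dyads) with high-dimensional compositional
    covariates such as oral microbiome feature tables. Alternates between
    fitting an L1-penalized logistic random-intercept model within each
    cluster (adaptive Gauss-Hermite marginal likelihood, proximal-gradient
    optimization, AIC-guided penalty selection, unpenalized re-estimation on
    the selected support) and Euclidean k-means on each dyad's pair of
    predicted outcome probabilities, until cluster membership stabilizes.
    Includes microbiome feature-table filtering, a synthetic dyad data
    generator with known truth, post-clustering caries summaries with
    Benjamini-Hochberg-controlled cross-cluster comparisons, and compact
    community-ecology statistics (Shannon index, Bray-Curtis distance, PCoA,
    PERMANOVA).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    statmod,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    lme4,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
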
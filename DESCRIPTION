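Package: mfindex
Title: Statistical Indices of Masculinity-Femininity from Multivariate Trait Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes four complementary masculinity-femininity indices from
    multivariate trait profiles with binary sex labels: sex-directionality
    (projection on the centroid axis weighted by Cohen's d), sex-typicality
    (linear discriminant scores normalized to unit within-sex variance),
    sex-probability (classification probability under equal priors), and
    sex-centrality (normalized difference of Mahalanobis distances to the two
    sex centroids). Classifies concordant versus discordant profiles, reports
    bias-corrected Mahalanobis distances between centroids, corrects trait data
    for measurement error via data-matrix disattenuation, and provides a
    Monte-Carlo harness for studying how trait reliability degrades index
    validity, including a vine-method random correlation sampler.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
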
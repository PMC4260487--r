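Package: tvbounds
Title: Time-Varying Decision Boundaries for Diffusion Models of Choice and
    Response Time
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward and inverse first-passage-time machinery for two-choice
    Wiener diffusion models with arbitrary time-varying decision boundaries.
    Computes choice probabilities and defective response-time distributions
    from given boundaries by stepping the coupled second-kind Volterra
    integral equations with a singularity-removed kernel, and recovers the
    time-varying boundaries that generate given choice and response-time
    distributions by point-wise grid search with piecewise-linear corrective
    refinement. Includes a Gaussian accumulator (race) model whose predictions
    can be equated to a diffusion process with time-varying boundaries, and an
    empirical pipeline that shifts raw response times, fits shifted Weibull
    distributions, assesses fit by decile chi-square, and inverts the smoothed
    distributions under a zero-drift assumption.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    fitdistrplus,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
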
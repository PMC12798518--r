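Package: prevbayes
Title: Bayesian Prevalence Estimation with Priors Elicited from
    Administrative Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the prevalence of a binary condition by combining
    self-reported outcome data with beta priors elicited from administrative
    case counts under a conjugate beta-Bernoulli model. Provides exact
    conjugate posteriors, an adaptive random-walk Metropolis sampler with
    rank-normalized split R-hat and bulk/tail effective-sample-size
    convergence diagnostics, a frequentist identity-link comparison, an
    administrative case-ascertainment algorithm (inpatient/outpatient claims
    with a 24-month window and 5-year lookback), deterministic record
    linkage with deduplication, and a synthetic linked-cohort generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
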
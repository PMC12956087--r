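Package: cfrsim
Title: Monte Carlo Simulation of Phased Alerting Policies for Community
    First Responders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate smartphone alerting policies for community
    first responder (CFR) systems attending out-of-hospital cardiac arrest.
    Volunteer locations are sampled uniformly in a dispatch disk around the
    patient, view delays and accept/reject/not-seen replies are drawn from
    historical response logs (bootstrap) or a calibrated synthetic model,
    and a nested Monte Carlo engine scores alerting policies (send-all,
    send-n, keep-n-active, batched) on survival, coverage, alert volume and
    redundant volunteer arrivals, converting first CPR times to survival via
    a logistic survival curve.
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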
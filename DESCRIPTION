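Package: vamalign
Title: Version Alignment for Grouped Survey Data Across Questionnaire Revisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal surveys whose closed-ended, interval-coded
    ("grouped data") questions were revised mid-study.  Implements the Version
    Alignment Method (VAM): the cohort transition matrix spanning a revision is
    decomposed into a time-related factor and a revision-related factor by
    minimising weighted slack variables under column-stochasticity and
    similarity constraints, and the revision factor is then used to express all
    responses on a single questionnaire version.  Also provides mean estimation
    from grouped data by the midpoint method and by grouped multinomial maximum
    likelihood under a latent Gamma distribution, ideal revision matrices from
    a fitted latent distribution, gap smoothing of discontinuous option
    intervals, a simulator of binned longitudinal responses with known ground
    truth, bootstrap confidence intervals for distances between probability
    vectors, and trend regression on annual means.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    boot,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
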
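Package: nirscoupling
Title: Coupling-Function Analysis of Cerebral Oxygenation and Arterial Blood Pressure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses cerebral autoregulation from simultaneous functional
    near-infrared spectroscopy (fNIRS) and continuous arterial blood pressure
    (ABP) recordings. Provides signal preprocessing (spike smoothing, cubic
    spline motion-artifact correction, anti-aliased downsampling), tissue
    oxygenation index computation, instantaneous phase extraction by complex
    Morlet continuous wavelet transform, dynamical Bayesian inference of
    phase-oscillator coupling functions between the cardiac ABP oscillation
    and slow oxyhemoglobin oscillations, coupling strength and directionality
    metrics, and cohort-level statistics (one-way ANOVA with Bonferroni
    pairwise tests, Pearson correlation, ROC analysis with Youden's J).
    Includes a synthetic-cohort generator with known ground-truth coupling
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    car,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
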
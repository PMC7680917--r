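Package: oscnet
Title: Classification with Small Networks of Coupled Photosensitive Chemical Oscillators
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates small networks of illumination-controlled Oregonator
    (Belousov-Zhabotinsky) oscillators used as classifiers of points in the
    unit square. Inputs are encoded as per-oscillator illumination switch-off
    times, networks are integrated with a fixed-step fourth-order Runge-Kutta
    scheme, and the output is read out as the number of activator maxima on a
    selected oscillator. Provides the mutual-information network fitness, an
    evolutionary optimizer for the seven adjustable network traits, generators
    for the Japanese-flag, French-flag and horned-region benchmark problems,
    and configuration-driven reproducible experiment runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
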
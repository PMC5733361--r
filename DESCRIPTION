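Package: stimsyn
Title: Component-Based Synthesis of Visual Stimuli with Reproducible
    Randomness and Real-Image Post-Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An offline, deterministic engine for synthesising visual
    stimulus movies from composable stimulus building components (SBCs):
    shape and pattern primers evaluated pointwise at every pixel, decorated
    with motion, temporal modulation and coordinate warps, mixed through a
    foreground/mask/background template, and post-processed by spatial
    filtering (direct or FFT-domain convolution, difference-of-Gaussians,
    Gabor, median), causal temporal filtering (windowed convolution or a
    recursive linear time-invariant state system built from complex
    exponentials), tone mapping (contrast stretching, sigmoid, histogram
    equalization, renorming), and display gamma compensation.  Random
    checkerboard stimuli are driven by a seeded xorshift128 grid generator
    whose streams are exactly reproducible and exportable as text.
    Sequences are described by a declarative YAML configuration and emit
    frame files (16-bit PNG or raw float stacks) together with a
    frame-accurate event log standing in for hardware synchronisation
    signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
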
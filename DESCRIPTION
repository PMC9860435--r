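Package: octotrigger
Title: Motion-Triggered Underwater Camera-Trap Engine with a Synthetic
    Benthic-Scene Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hardware-independent re-implementation of the acquisition
    engine of a triggered underwater camera trap. Provides the full
    motion-detection pipeline (Gaussian blur, region-of-interest crop,
    per-pixel mixture-of-Gaussians background subtraction, morphological
    mask merging, connected-component trigger evaluation, contrast-limited
    adaptive histogram equalization), the deployment state machine
    (intervalometer and triggered modes, rest periods, voltage and storage
    exit conditions, deployment folders and logs), an INI-style
    configuration system, a deterministic synthetic seafloor-scene
    simulator with ground truth, and trigger-performance scoring. All
    timing is driven by a simulated clock so multi-day deployments replay
    in seconds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    generics,
    ggplot2,
    jpeg,
    png,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
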
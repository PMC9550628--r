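Package: etsted
Title: Event-Triggered STED Microscopy: Detection Pipelines, Calibration and
    Closed-Loop Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hardware-free implementation of the computational core of
    event-triggered STED (stimulated emission depletion) imaging: real-time
    event-detection pipelines over widefield timelapses (ratiometric intensity
    spikes, slowly rising signals, vesicle proximity), third-order polynomial
    calibration between widefield and scan coordinate systems, a closed-loop
    acquisition controller driven by a ground-truth synthetic scene simulator,
    and post-acquisition quantification (dF/F0 traces, detection-quality
    ratios, cluster segmentation, track linking and mean-squared-displacement
    analysis). All tabular results are tibbles so analyses compose with the
    pipe; fitted objects have broom-style tidy() and glance() methods and
    ggplot2 autoplot() methods.
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
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
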
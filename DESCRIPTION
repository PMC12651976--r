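Package: restoselect
Title: Texture-Based Classification of Dental Restorations on Panoramic
    Radiographs with Hybrid Wrapper Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-class image-level classifier bank for dental restorations
    (filling, implant, root canal, bridge, crown) on panoramic radiographs.
    Implements radiograph enhancement (centered crop, global histogram
    equalization, CLAHE), global grey-level co-occurrence matrix (GLCM)
    texture descriptors, hybrid grey-wolf/particle-swarm (HGWO-PSO) binary
    wrapper feature selection driving an RBF support vector machine,
    conventional machine-learning baselines, and a leakage-safe patient-level
    evaluation harness with grouped cross-validation and stratified bootstrap
    confidence intervals. Ships a calibrated synthetic phantom-image generator
    so the whole pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tools,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
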
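Package: pillarbeat
Title: Contractile Force and Calcium Transient Analysis for Pillar-Based
    Engineered Heart Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Video-based contractility analysis for engineered heart tissue
    (EHT) suspended between elastic PDMS pillars, and kinetic analysis of paced
    calcium transients. Pillar-head motion is tracked to subpixel precision by
    phase-only correlation, converted to force with a cantilever-beam model
    (deflection = P*L^3/(3*E*I), I = pi*d^4/64), and summarised per beat.
    Fluorescence traces are normalised to dF/F0, segmented into paced beats,
    and reduced to amplitude, time to peak, and the 80%-decay time per region
    of interest. A synthetic-data generator produces pillar-deflection videos
    and paced fluorescence traces with exact ground truth, so every stage of
    the pipeline can be validated end to end, and a simulation harness
    supports two-group comparisons with Student's t tests.
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
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
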
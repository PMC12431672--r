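Package: fdflim
Title: Widefield Frequency-Domain Fluorescence Lifetime Image Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of widefield frequency-domain
    fluorescence lifetime imaging (FD-FLIM) data. Generates homodyne
    phase-stepped image stacks for fluorophore solutions, resolution
    targets and two-population cell scenes; demodulates stacks into
    per-pixel phasor fields; calibrates against a reference fluorophore
    of known lifetime to produce phase and modulation lifetime maps;
    performs flat-field correction, Otsu foreground masking, masked
    lifetime summaries and the photon-economy F-score; measures lateral
    resolution from edge-spread profiles; and compares image-level
    lifetimes across groups with one-way ANOVA and Tukey-Kramer post hoc
    tests. Designed around the phasor representation of single-frequency
    homodyne FLIM of metabolic autofluorescence (NADH, FAD).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
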
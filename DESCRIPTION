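Package: ethoquant
Title: Quantification Toolkit for In Vitro Ethanol Exposure Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reusable, tested implementations of the bespoke computations used
    in multi-channel immunocytochemistry studies of ethanol-exposed neuronal
    cultures: fixed-threshold percent-area segmentation and mask-overlap
    colocalization metrics, live/dead ratio quantification, delta-delta-Ct
    relative qPCR quantification with NormFinder-style reference-gene
    stability selection, physiological ethanol dosimetry unit conversions
    (brain/serum/blood/BAC), and an assumption-gated statistical routing
    layer (Levene and Shapiro-Wilk gates into ANOVA with Dunnett, Sidak or
    Tukey post hocs, Welch/Brown-Forsythe with Dunnett T3, or Kruskal-Wallis).
    A seeded synthetic-data generator produces ground-truthed image fields
    and Ct tables so every pipeline stage is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    png,
    jsonlite,
    withr,
    car,
    multcomp,
    emmeans,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
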
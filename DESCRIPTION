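Package: phasekit
Title: Sequence Grammar and Live-Cell Phase-Separation Analytics for TDP43
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to dissect how the intrinsically disordered C-terminal
    domain (CTD) of TDP43 encodes condensate formation and dynamics, and to
    relate phase behaviour to splicing function. Provides evolutionary
    sequence analytics for disordered regions (normalized edit distances,
    composition profiles, sliding-window hydropathy on rescaled
    hydrophobicity scales, hydrophobic-cluster detection and spacing,
    constraint-preserving mutant design including cluster regrouping),
    quantification of nuclear condensates in fluorescence images (nuclear
    segmentation, droplet detection, condensed/diffuse classification,
    saturation-concentration estimation, GFP concentration calibration,
    phase-onset analysis), half-bleach FRAP recovery normalization and
    exponential fitting, single-cell ratiometric splicing analysis of
    three-colour flow cytometry data, and seeded synthetic-data generators
    with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
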
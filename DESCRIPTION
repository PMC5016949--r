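Package: chromotrack
Title: Statistics for Two-Colour 3D Chromatin Locus Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of two-colour 3D live-cell tracking of fluorescently
    tagged chromatin loci: inter-channel (chromatic) alignment and
    measurement-error estimation from a colocalising control, quality-control
    filtering on axial position, spot intensity and contrast, inter-locus
    distance and chromatin compaction summaries, a two-dimensional
    Kolmogorov-Smirnov orientation-anisotropy statistic, the RV coefficient of
    coupled locus motion, mean square change in distance (MSCD) curves with a
    bootstrap between-cell baseline, and a mother/daughter compaction
    inheritance test. Includes a seeded synthetic trajectory generator
    (mean-reverting confined motion with localisation noise and channel
    offsets) so the full pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
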
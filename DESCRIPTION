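Package: discquant
Title: Quantitative Analysis of Clonal Tumor Growth in Drosophila Imaginal Disc Stacks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for quantifying GFP-labelled mutant clones in
    3D confocal stacks of Drosophila eye-antennal imaginal discs: supervised
    voxel classification of clone regions, DAPI-based tissue masking,
    per-clone volumetry and tumor-volume percentages, phospho-histone H3
    spot counting partitioned inside/outside clones with per-mm3
    normalisation, transcription-factor signature clustering of expression
    profiles (1-Pearson / Euclidean distances), and cohort statistics
    (eclosion rates, Kruskal-Wallis with Dunn's post hoc, one-way ANOVA with
    Dunnett's comparisons). Includes a synthetic phantom and count-matrix
    generator with full ground truth so the whole pipeline is testable
    without raw imaging or sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    ranger,
    jsonlite,
    tiff,
    ape
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
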
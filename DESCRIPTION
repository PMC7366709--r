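Package: octaquant
Title: Quantitative Analysis of OCT-Angiography Foveal Microvasculature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the foveal microvasculature on en-face optical
    coherence tomography angiography (OCTA) images: adaptive (Bradley
    variant, integral-image) and global (IsoData) binarization, Zhang-Suen
    skeletonization with junction clustering, branching-point density,
    total vessel length, vessel density, and foveal avascular zone (FAZ)
    area from manual polygon tracings or an automated flood-fill stand-in.
    Includes a ground-truthed synthetic angiogram generator (space
    colonization capillary networks with a planted avascular zone and
    perifoveal arcade), a cohort simulator for sickle-cell retinopathy
    genotype groups, and the matching nonparametric statistics
    (Mann-Whitney U with exact enumeration, tie-corrected Kruskal-Wallis,
    two-way random-effects consistency ICC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
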
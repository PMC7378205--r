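Package: nemascreen
Title: Miniaturized C. elegans Screening Analytics for Survival and Nile Red Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for miniaturized whole-organism screening in
    Caenorhabditis elegans. Quantifies vital Nile red fluorescence from
    single-worm micrographs by texture-based pixel classification (local
    entropy features feeding a pruned decision tree), size filtering of
    candidate regions, isodata binarization and white-pixel counting;
    analyses liquid-culture survival logs by DT50 estimation with one-way
    ANOVA and Dunnett's post-test; normalizes plate-level fluorescence to
    a vehicle control with Bonferroni-corrected comparisons; and combines
    both assays into screening verdicts (dual-active, fat-reducer,
    lifespan-extender, toxic). A synthetic-data module generates
    ground-truth worm images and simulated survival and plate experiments
    so the whole pipeline runs and is validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    multcomp,
    EBImage,
    tiff,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
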
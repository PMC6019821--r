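Package: ethnophylo
Title: Phylogenetic Dispersion and Hotnode Analysis of Ethnomedicinal Plant Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the phylogenetic structure of ethnomedicinal
    plant use and its relationship to pharmacological research effort.
    Provides standardized-effect-size dispersion metrics (MPD/MNTD with a
    tip-label shuffling null, reported as NRI/NTI), permutation-based
    per-node over-representation ("hotnode clade") detection, grafting of
    unsampled species onto a genus-level backbone phylogeny, deterministic
    mean-path-length ultrametricization, rank-based association tests with
    exact small-sample p-values, inside/outside-hotnode summary reporting,
    and a synthetic tree-and-trait generator with known phylogenetic
    structure for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
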
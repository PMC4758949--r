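Package: supprox
Title: Residue Proximity from Saturation-Suppressor Mutagenesis and
    Structural Model Discrimination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns deep-mutational-scanning read counts and
    saturation-suppressor screens into residue-level quantities for
    structural model discrimination. Computes per-mutant mutational
    sensitivity scores from expression-level read counts, aggregates them
    into per-position RankScores, and classifies suppressors as proximal
    or distal. Scores decoy structural models against experimentally
    derived residue-contact constraints (ContactScore), against the
    correlation of RankScore with residue depth (rdepthscore), and
    against deviation from reference packing (the R_s statistic).
    Identifies differential contacts between two rival structures of one
    protein and judges which structure a set of suppressor pairs
    supports. Includes residue-level geometry (side-chain centroids,
    Kabsch superposition, Shrake-Rupley solvent accessibility, residue
    depth), a four-parameter sigmoid fit for thermal melt curves, and
    seeded synthetic-data generators for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
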
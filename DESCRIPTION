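Package: crisprtiles
Title: CRISPR Tiling-Screen Scoring, Structure Mapping and Docking-Box Definition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of pooled CRISPR tiling screens from raw sgRNA count
    tables to structure-guided virtual screening. Computes reads-per-million
    normalization, library quality control, log10 fold changes with
    low-frequency filtering, control-calibrated normalized CRISPR scores
    (NCS), Gaussian-smoothed per-residue essentiality profiles and
    CRISPR-hypersensitive segment calls; maps profiles onto PDB/mmCIF
    structures (Chimera attribute files, B-factor annotation); defines
    axis-aligned docking boxes around hypersensitive residues with a
    grid-based buriedness cavity detector; parses and ranks docking-engine
    scores; and analyses companion assays (viability normalization,
    NanoBRET ratios, Boltzmann thermal-shift fits, four-parameter logistic
    dose-response). Seeded simulators generate screen counts, tiling scans
    with planted segments, toy structures, and melt curves for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
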
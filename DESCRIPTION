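Package: cfrckit
Title: Classification of Crustacean CHH-Family Neuropeptide Receptor Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in silico screening and classification of crustacean
    CHH-family G protein-coupled receptor candidates (CFRCs). Implements the
    candidate curation chain (e-value screen, Class A/7tm_1 domain check,
    transmembrane-count filter with brachyuran fragment exemptions, same-species
    redundancy removal), seven-transmembrane topology delineation from per-residue
    labels or a hydropathy fallback, a degenerate motif grammar with
    anchor-cysteine matching for ECL2/ECL3 subclade diagnostics, Class A signature
    scans (E/DRY, TxP, CWxP, NPxxY, ECL1 xWxF), CHH-superfamily peptide typing
    (six-cysteine framework, disulfide connectivity, Type I/II Gly rule, mature
    peptide extraction), alignment column profiles and consensus/logo derivation,
    species-by-subclade presence matrices with summary statistics, and a seeded
    synthetic benchmark generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
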
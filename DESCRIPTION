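Package: phosphostate
Title: Condition-Resolved Phospho-Site Analysis of Targeted Proteomics PSM Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of PSM-level (peptide-spectrum match) exports
    from affinity-purification phospho-proteomics experiments on a single
    target protein. Performs in-silico tryptic digestion and peptide-to-protein
    mapping, per-residue coverage and depth profiling, localization-confidence
    filtering of phospho-sites, cross-condition classification of sites
    (shared, mitotic-arrest-shared, condition-unique), MELT-motif
    phosphorylation counting, and pseudocount fold-change matrices for
    co-purifying interactors. Includes a synthetic PSM generator with planted
    ground-truth sites for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
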
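Package: pipflank
Title: Sequence Features, Flanking Charge and Binding Affinity of PCNA-Interacting Motifs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of PCNA-interacting short linear motifs
    (PIP-box, PIP-degron and APIM): motif coordinate assignment and
    classification, motif-set degeneracy statistics and sequence-logo
    information content, pH-dependent net charge per residue (NCPR) of
    motif-flanking regions, NMR secondary-chemical-shift helicity
    estimation, fitting of SPR steady-state and single-cycle kinetic
    series and of reverse-titration ITC one-set-of-sites isotherms, and
    regressions between sequence features and ln(KD). Seeded synthetic-data
    generators emulate every instrument input with known ground truth so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    tibble,
    utils
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
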
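Package: clockworks
Title: Circadian Multi-Omics Analysis of SCN Explants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for circadian timekeeping in suprachiasmatic
    nucleus (SCN) explants. Calls circadian features on one-cycle, replicated
    SILAC proteome time courses with a dual criterion combining a JTK-style
    Kendall-tau test and an umbrella (Mack-Wolfe) trend test over a shared
    permutation null; assembles quantified proteomes under replicate-based
    filters; annotates single-cell clusters by marker genes, computes two-gene
    co-expression partitions, interactor expression profiles and day/night
    differential expression; performs hypergeometric over-representation
    analysis on user-supplied gene sets; and quantifies bioluminescence and
    fluorescence traces under pharmacological treatment (period, phase shift,
    normalized amplitude, B/A washout ratio, relative amplitude error,
    Rayleigh statistics, 24-h signal integration, pseudo-alignment). A
    synthetic-data module generates traces, proteome tables and cell-by-gene
    count matrices with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
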
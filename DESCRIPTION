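Package: hempcw
Title: Cell Wall Composition and Stem Morphometry Phenotyping for Hemp Fibre Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts raw assay measurements from hemp (Cannabis sativa) stem
    phenotyping into derived fibre-quality traits. Covers sugar-recovery-standard
    corrected monosaccharide composition of the alcohol-insoluble residue (AIR),
    gravimetric Klason lignin and cell-wall content, crystalline cellulose and
    mannan fractions from sequential weak/strong acid hydrolysis, and stem
    cross-section morphometry under an annulus model (lumen, woody core, primary
    and secondary bast fibre). Includes technical-replicate repeatability
    statistics (coefficient of variation), between-accession one-way ANOVA with
    significance coding, significance-masked Pearson correlation matrices, a
    synthetic-study generator with known truth for validation, and transcribed
    reference tables from a six-accession fibre hemp panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
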
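Package: pangem
Title: Pan-Genome Phenotyping and Strain-Specific Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-strain systems-biology toolkit: calls binary growth
    phenotypes from kinetic phenotype-microarray traces (Savitzky-Golay
    smoothing, one-sided z-test against pooled negative controls with
    Bonferroni correction), clusters protein sequences into gene families
    and builds pan-genome presence matrices with ordered core-genome
    curves and strain blocks, enumerates alleleomes (unique amino-acid
    variants per family) with dominant-allele and clade analysis, and
    derives strain-specific genome-scale metabolic models from a
    pan-model via reciprocal-best-hit orthology, GPR-driven pruning,
    flux balance analysis, and minimum-cardinality gap-filling, scored
    against observed phenotypes. Includes a seeded synthetic-data
    generator with full ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    signal,
    vegan,
    ape,
    phangorn,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    pracma,
    boot
Config/testthat/edition: 3
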
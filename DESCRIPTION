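Package: kaksess
Title: Evolutionary Conservation of Essential Versus Nonessential Bacterial Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparing the evolutionary conservation of
    essential and nonessential bacterial genes. Pairs each gene with its best
    ortholog in a homologous strain, builds a protein-guided codon alignment,
    and estimates Ka, Ks and Ka/Ks with a from-scratch Nei-Gojobori (1986)
    pathway-counting estimator with Jukes-Cantor correction. Downstream
    analyses include per-organism essential-versus-nonessential comparisons
    (Mann-Whitney U tests, half-sampling bootstrap, cross-organism paired
    t-test), a COG-subcategory significance matrix with a conserved-subcategory
    rule, and a classifier for persistent nonessential (PNE) genes. A seeded
    codon-evolution simulator generates complete multi-organism input panels
    with controlled dN/dS structure so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
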
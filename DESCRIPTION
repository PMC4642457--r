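Package: mitorho
Title: Mitogenome Lineage Classification, Founder-Age (Rho) Dating and
    Haplogroup Phylogeography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for human mitochondrial DNA lineage analysis in the
    forensic and phylogeographic tradition: parsing and formatting of
    rCRS-relative variant nomenclature, hotspot masking, haplogroup
    classification against a motif tree with private-mutation extraction,
    within-clade maximum-parsimony genealogies, founder-age estimation with
    the rho statistic, its heuristic standard error and the star index under
    explicit molecular clocks, control-region motif searches over haplotype
    databases, ordinary kriging of haplogroup frequency surfaces, and a
    seeded synthetic-data generator (Poisson mutation accumulation on star
    and coalescent genealogies) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
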
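Package: metastrack
Title: Multi-Sample Tumor Phylogenetics and Metastatic Migration Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Reconstructs metastatic tumor evolution from jointly called
    multi-sample somatic variants and copy-number segments. Provides somatic
    variant filtering against matched normals, 1-Mb copy-number profile
    clustering and allele-specific CNV/LOH inference from inherited
    heterozygous variants, perfect-phylogeny sample trees under the infinite
    sites assumption, subclone reconstruction by variant-allele-frequency
    clustering with purity-corrected cellular prevalences and exhaustive
    tree enumeration, and classification of metastatic seeding events
    (monoclonal, polyclonal, recolonization), subclonal incubator sites and
    metastatic wave ordering. Ships a synthetic multi-site cohort simulator
    with full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
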
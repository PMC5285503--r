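Package: hhkmine
Title: Mining Proteomes for Hybrid Histidine Kinases and Hormone-Receptor Homologs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for mining protein sets for hybrid histidine
    kinases (HHKs) and for calling plant-hormone-receptor homologs
    (ethylene-receptor-like and cytokinin-receptor-like HHKs) from domain
    architecture and conserved-residue diagnostics. Domains are detected with
    position-specific scoring matrices calibrated to empirical E-values,
    transmembrane helices with a Kyte-Doolittle hydropathy scanner, and
    candidate architectures are classified with an explicit grammar
    (canonical hybrid core, truncations, ethylene subfamilies 1/2,
    TM-flanked CHASE cytokinin receptors, phytochromes, dual kinases,
    osmosensing group III). A distance-based phylogeny stage with bootstrap
    support and a synthetic-proteome generator with planted ground truth make
    the whole pipeline exercisable end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
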
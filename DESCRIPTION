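Package: gutflux
Title: Diet-Constrained Metabolic Modelling and Reaction Abundance
    Profiling of the Gut Microbiome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the metabolic capacity of the gut
    microbiome shifts in metabolic disease. Provides genome-scale
    metabolic model (GEM) input/output and validation, diet-constrained
    flux balance analysis with a built-in bounded-variable simplex
    solver, differential abundance testing of metagenomic species
    pan-genomes (Wilcoxon rank-sum with Benjamini-Hochberg control and a
    zero-median selection rule), per-sample reaction-abundance
    ("reactobiome") profiling with cross-disease intersection and KEGG
    ortholog mapping, personalised multi-species community models with a
    shared lumen compartment and abundance-coupled biomass, association
    of reaction abundances with plasma metabolite levels, and a
    synthetic-data generator that emulates the statistical structure of
    case/control metagenome cohorts so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
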
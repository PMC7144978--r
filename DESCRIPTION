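Package: phenogenon
Title: Gene-Phenotype Association and Mode-of-Inheritance Prediction from
    Phenotype-Annotated Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Phenogenon", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores gene-phenotype associations in cohorts of unrelated,
    exome-sequenced patients annotated with Human Phenotype Ontology (HPO)
    terms. Variants are binned on a genotype-frequency by CADD grid, each bin
    is tested for case enrichment with a one-sided Fisher exact test, and the
    rare-bin signal is collapsed into an HPO goodness-of-fit (HGF) score via a
    scaled weighted Stouffer combination. A signal-ratio-weighted M score
    predicts the mode of inheritance (dominant versus recessive, with
    compound-heterozygote handling). Includes a self-contained synthetic
    cohort simulator (ontology, genotypes, gnomAD-style annotations,
    phenotypes, truth set) so the full pipeline is testable without patient
    data, plus benchmarking against Fisher's-method and HGF-only comparator
    models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
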
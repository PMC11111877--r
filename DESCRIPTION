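Package: plasticmod
Title: Multi-Omics Function-Module Discovery and Lineage-Plasticity Scoring
Version: 0.1.0
Authors@R: person("Plasticmod", "Developers", role = c("aut", "cre"),
    email = "maintainers@plasticmod.dev")
Description: A reusable pipeline for clustering multi-omics gene-set
    enrichment results into function modules and scoring sample-level
    lineage plasticity. Enrichment is hypergeometric with
    Benjamini-Hochberg correction; enriched terms are clustered by
    Cohen's kappa agreement over gene membership followed by
    neighbor-joining tree construction and a longest-branch tree cut.
    Sample scoring uses single-sample GSEA (ssGSEA), gene-trait
    correlation with positive-value retention, and preranked GSEA with
    leading-edge extraction. Additional modules provide copy-number
    segment categorization and association tests, mutation-stratum
    enrichment, a fixed five-lncRNA linear survival risk score with
    Harrell's concordance index, and regulon-based transcription-factor
    activity inference. A synthetic-data generator with planted
    structure makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    phangorn,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
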
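Package: diallelkit
Title: Combining Abilities, Inheritance Modes and Mixed-Model GWAS for
    Diallel Hybrid Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for diallel crossing panels of homozygous
    founders, as used to dissect complex traits in yeast natural isolates.
    Implements Griffing's combining-ability decomposition with broad- and
    narrow-sense heritability estimation, mid-parent-value classification of
    inheritance modes (additivity, partial/complete dominance,
    over/underdominance), in-silico hybrid genotype construction with site
    filtering and long-range linkage-disequilibrium pruning, and mixed-model
    genome-wide association with leave-one-chromosome-out kinship, additive
    and overdominant genotype encodings, permutation-based family-wise
    significance thresholds, Cohen's d effect sizes and low-frequency-variant
    enrichment summaries. A synthetic-data generator with known genetic
    architecture makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
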
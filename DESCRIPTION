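Package: postgwas
Title: Post-GWAS Interpretation of Reported Asthma Risk Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for interpreting published genome-wide association results
    for a common disease: haplotype-based linkage-disequilibrium (r2)
    computation with greedy P-value-ordered clumping and proxy lookup;
    per-variant liability-scale variance explained and cohort heritability
    accounting under the logistic liability model; non-centrality-parameter
    power comparison across case-control designs under the liability-threshold
    model with ascertainment; Bonferroni-corrected direction-aware replication
    assessment with genomic-inflation adjustment; sentinel-eQTL selection and
    LD-proxy target-gene assignment; and citation-count gene classification.
    A seeded synthetic-data module generates block-structured haplotype
    panels, liability-threshold case-control summary statistics and planted
    cis-eQTLs so the full pipeline runs without external downloads; the
    published asthma tables are bundled as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
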
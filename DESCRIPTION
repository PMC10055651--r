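Package: imprintscope
Title: 11p15.5 Imprinting Status, Somatic Mosaicism and Paired-Tumor
    Concordance Analysis for Bilateral Wilms Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the genetic and epigenetic predisposition to
    bilateral Wilms tumor. Classifies 11p15.5 imprinting status (retention of
    imprinting, loss of imprinting, copy-neutral loss of heterozygosity) from
    EPIC-style methylation beta values over the H19/ICR1 and KCNQ1OT1/ICR2
    imprinting control regions, estimates tissue-level mosaic fractions from a
    cell-population mixture model, detects copy-neutral LOH on 11p from
    B-allele-fraction tracks, partitions somatic variants of paired synchronous
    tumors into shared and private sets, triages annotated germline variants
    through a panel/ClinVar/in-silico/VAF-enrichment decision tree, and fits a
    control-calibrated age-methylation drift model for blood leukocyte DNA.
    Ships a synthetic cohort generator that emulates pre- versus
    post-lateralization embryonic events so the whole pipeline is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
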
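Package: methylmiR
Title: Integrative DNA Methylation and miRNA Expression Analysis for
    Promoter Hypermethylation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying epigenetic silencing of intragenic
    microRNAs through promoter CpG-island hypermethylation, as applied to
    miR-486-5p and its ANK1 host gene in osteosarcoma. Implements
    in-silico bisulfite conversion and methylation-specific PCR (MSP)
    template evaluation, semi-quantitative bisulfite-sequencing trace
    calling, quantitative MSP percent-of-methylated-reference (PMR)
    scoring with cohort-derived thresholds, comparative-CT qPCR relative
    quantification with demethylation-induction criteria, Illumina-style
    Beta-value processing and quantile normalisation, methylation versus
    expression integration, the small-sample statistics the analyses
    rely on, and a seeded synthetic cohort generator so every stage runs
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
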
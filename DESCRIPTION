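Package: epimutr
Title: Case-Control Epimutation Discovery from DNA Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An epigenome-wide association study (EWAS) toolkit for
    discovering promoter CpG-island epimutations from methylation-array
    beta values. Implements per-probe case-control t-testing with
    Bonferroni correction, windowed smoothing of -log10 P-values,
    principal-component quality control, three-state methylation
    classification (fully unmethylated / hemimethylated / fully
    methylated), and island-level epimutation calling designed around the
    dual MMACHC/TESK2-promoter signature of the epi-cblC disorder. Also
    provides the companion rules for assigning de novo reconstructed
    transcripts to known genes from tabular alignment records, gene-level
    TPM aggregation, reference-normalized relative expression from qPCR
    quantification cycles, and a beta-value simulator that reproduces the
    statistical structure of a 17-case versus 350-control methylome study
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
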
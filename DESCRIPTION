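Package: eradscreen
Title: Substrate Discovery from Label-Free SEL1L IP-MS Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies candidate substrates of the SEL1L-HRD1 ER-associated
    degradation (ERAD) complex from label-free anti-SEL1L
    immunoprecipitation mass spectrometry screens. Starting from
    peptide-spectrum-match (PSM) count tables across four pulldown genotypes
    (IgG control, SEL1L knockout, wild type, HRD1 knockout) and replicate
    experiments, the package computes PSM enrichment features, fits a
    three-parameter logistic confidence score by gradient ascent on a smooth
    Matthews-correlation-coefficient surrogate, anchors the score cutoff on
    hits detected exclusively in HRD1-knockout samples, applies a hard filter
    cascade with reference-protein enrichment ratios, requires consensus
    across replicate experiments, removes transcriptionally upregulated
    hits using RNA-seq differential expression, and catalogs shared versus
    cell-type-specific candidates across cell types via ortholog mapping and
    normalized-count pathway overrepresentation. A seeded negative-binomial
    simulator generates synthetic screens with planted ground truth for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
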
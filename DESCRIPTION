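Package: splicefate
Title: Fate of Aberrantly Spliced Transcripts: Translation, Proteome and
    Metabolic Readouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for studying the fate of aberrantly spliced
    transcripts induced by mutant splicing factors (e.g. SF3B1 hotspot
    mutants). Quantifies aberrant versus canonical splice-junction usage
    from polysome-profiling count data, computes per-junction
    translation-efficiency log-ratios with exact-test significance and
    classifies junctions into more-translated (group A) and
    less-translated (group B) sets; annotates cryptic 3' splice-site
    junctions by reading frame, premature termination codons and
    predicted nonsense-mediated-decay (NMD) sensitivity under the 50-nt
    rule; filters and calls label-free proteome differential abundance
    and computes splice/proteome overlaps; and parameterizes metabolic
    assays (extracellular-flux respiration parameters, four-parameter
    logistic IC50 fits, percent-change statistics). A synthetic-data
    module generates all inputs with planted ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
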
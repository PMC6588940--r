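Package: srnabench
Title: Bias Benchmarking for Small RNA Sequencing with Ground-Truth Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and dissect technical bias in small RNA
    sequencing. Provides a ground-truth read simulator that emulates an
    equimolar synthetic miRNA pool prepared with ligation-based, degenerate
    adapter (UMI-tagged), or template-switch library chemistries, with
    configurable adapter-ligation, reverse-transcription and PCR bias,
    PCR duplication and stutter, isomiR-generating artifacts and sequencing
    error; kit-aware adapter trimming and UMI extraction; isomiR-aware read
    assignment; directional UMI deduplication; median-of-ratios
    normalization; accuracy, detection-diversity, false-isomiR and
    batch/triplicate consistency metrics; and type-II sum-of-squares
    decomposition of per-sequence variance into sequence characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
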
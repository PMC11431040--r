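Package: mprtseq
Title: Multi-Primer Reverse-Transcription Mapping of mRNA Degradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping mRNA chain breaks at single-nucleotide
    resolution from multi-primer reverse-transcription (MPRT-seq) read-outs.
    Converts per-primer RT-stop peak tables into assembled, normalized,
    control-subtracted degradation-reactivity profiles; calls
    degradation-sensitive hotspots against a rescaled-average baseline;
    computes fold-change and base-composition statistics; annotates hotspot
    calls with secondary-structure context from dot-bracket input; and
    derives capillary-electrophoresis integrity metrics. A stress simulator
    generates fragment populations under freeze-thaw or thermal dosing with
    base- and structure-dependent cleavage propensities, so the whole
    pipeline can be exercised and validated without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
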
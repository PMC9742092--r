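Package: chipclipr
Title: Integrating ChIP-Seq and eCLIP Peaks with Differential Expression
    and Splicing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether a chromatin-associated RNA-binding
    protein regulates genes at both the transcriptional and the
    posttranscriptional level. Reads DESeq2-style differential expression
    tables, rMATS-style differential splicing tables, narrowPeak ChIP/eCLIP
    peak files and bedGraph coverage tracks; classifies peaks into genomic
    region classes with a deterministic priority scheme; computes
    region-composition enrichment against the genome background with
    one-tailed Fisher tests, region-level eCLIP fold-enrichment summaries
    and metagene signal profiles; and intersects the filtered layers into
    gene classifications, direct-target sets, ChIP-CLIP distance profiles,
    Jaccard co-occupancy statistics and a final co-regulated gene list.
    Includes a self-consistent synthetic data generator with a
    machine-readable truth manifest so the whole pipeline can be exercised
    and its recovery tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
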
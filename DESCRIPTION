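Package: dsbsirna
Title: Break-Induced Small RNA Coverage, RNAi Screen Scoring and Splicing qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying small interfering RNA (siRNA) formation at
    site-specific DNA double-strand breaks in Drosophila. Implements
    strand-resolved reads-per-million coverage around cas9 cut sites with
    sgRNA-peak exclusion and the upstream/downstream per-base density ratio;
    size-normalized per-feature (exon, intron, splice-junction) siRNA coverage
    with junction-spanning read classification on genomic and spliced axes;
    plate-median normalization, local tricube-weighted polynomial (LOESS)
    residual z-scoring and control-based candidate calling for genome-wide
    dual-luciferase RNAi screens; 2^-ddCt relative quantification and splicing
    efficiency from qPCR Ct tables; and seeded simulators that generate all of
    these inputs with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
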
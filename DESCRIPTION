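Package: nomeprofiler
Title: Nucleosome Occupancy and CpG Methylation Profiling from NOME-seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds transcription start site (TSS) anchored average profiles of
    nucleosome occupancy, CpG methylation and CpG density from per-site NOME-seq
    methylation calls (GpC accessibility and CpG methylation contexts), selects
    non-promoter control regions whose per-side CpG counts match each promoter
    by detecting and merging CpG clusters and shifting candidate centers, and
    stratifies regions by expression, CpG density and methylation. Includes a
    synthetic NOME-seq data generator with known ground truth (CpG islands,
    density-dependent methylation, a nucleosome-decreased region with phased
    downstream nucleosomes, binomial read sampling) so the whole pipeline runs
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Biostrings,
    IRanges,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
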
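Package: svidx
Title: Population-Scale Structural-Variant Evidence Indexing and Querying
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts discordant read-pair and split-read evidence of
    structural variants (SVs) from per-sample alignment files, builds a
    unified multi-sample interval index over the extracted evidence, and
    answers SV queries (deletion, duplication, inversion, break end) with
    per-sample counts of supporting alignments. Includes evaluation
    machinery for cohort-level benchmarking (confusion-matrix metrics,
    reciprocal-overlap set operations, germline filtering of somatic call
    sets against a panel of normals, query-resolution sweeps) and a
    coordinate-level paired-end cohort simulator with known SV genotypes
    so the whole extract-index-query-evaluate pipeline can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
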
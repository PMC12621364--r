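Package: panmeth
Title: Allele-Specific Pan-Methylome Analysis on Haplotype Sequence Graphs
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying allele-specific DNA methylation in
    parent-progeny trios using a haplotype-resolved sequence graph.
    Provides GFA input/output with node chopping and path-coordinate
    projection, parsing and uniting of per-clone bisulfite cytosine
    reports, graph-node methylation classification (core, dispensable
    and private nodes), window-based differential methylation testing
    with overdispersion correction and inheritance-set logic,
    single-reference bisulfite bias quantification and homology-based
    correction, gene-level methylation classification (gbM and teM)
    with metagene profiles, and a fully ground-truthed synthetic trio
    generator used to validate every step of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
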
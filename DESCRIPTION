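Package: nappan
Title: Pangenome Profiling of Bacterial Nucleoid-Associated Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pangenome-level censusing of bacterial
    nucleoid-associated protein (NAP) families. Validates domain-search
    hits against e-value/probability/coverage thresholds, clusters
    validated proteins into orthologous protein families (greedy identity
    clustering and bidirectional-best-hit triangles), computes
    frequency and paralogue indices with core/flexible pangenome
    partitioning, profiles molecular weight and isoelectric point,
    analyses 5-kb gene vicinities and origin-relative gene positions,
    associates NAPs with mobile genetic elements (plasmids, ICEs, IMEs)
    including inverted-repeat (oriT-like) detection, normalizes RNA-seq
    coverage to 1x genomic content (RPGC), and builds neighbor-joining
    trees from single-marker alignments. Ships a synthetic pangenome
    generator with planted ground truth so every stage is testable
    without external data, plus census fixtures for a 93-genome
    acidophile dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    phangorn,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
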
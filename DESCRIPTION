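Package: plastomics
Title: Chloroplast Genome Assembly from Total-DNA Mate-Pair Reads and
    Comparative Plastome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-guided assembly of quadripartite chloroplast genomes
    (LSC, IRa, SSC, IRb) from unfractionated total-DNA mate-pair short reads,
    and downstream comparative analysis. Provides quality filtering and
    intact-pair enforcement, a seed-and-extend short-read mapper for
    reference-anchored read selection, a de Bruijn graph contig assembler with
    mate-pair scaffolding, reference-collinear scaffold correction with
    single-N gap marking, primer design and gap closure with long finishing
    reads, inverted-repeat reconstruction, pairwise whole-genome alignment
    with transition/transversion and INDEL divergence statistics, and
    exhaustive maximum-parsimony phylogeny with bootstrap support. A
    synthetic-data module simulates plastomes, their evolution under
    controlled substitution and INDEL regimes, and total-DNA mate-pair
    libraries so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    ape,
    phangorn,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
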
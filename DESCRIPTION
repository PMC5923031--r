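Package: genemend
Title: Cross-Species Refinement of Gene Models by Alignment Consensus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corrects the intron/exon structure and start codons of annotated
    protein-coding gene models by maximising amino-acid multiple-alignment
    agreement across an orthogroup of single-copy genes from several species.
    Candidate exons are discovered by three-pass cross-species spliced
    alignment, partitioned into adjacency groups via maximal cliques of an
    alignment-overlap graph, and assembled left-to-right while splice
    junctions and start codons are locally optimised with a multipartite
    choice function over a BLOSUM62 column-score objective. Includes the
    matching evaluation metrics (splice-junction F-score, rolling-threshold
    coverage score, orthogroup localisation entropy), a synthetic orthogroup
    generator with controlled annotation errors, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
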
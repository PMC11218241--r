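Package: pangraft
Title: Gene-Order-Aware Refinement of Bacterial Pangenome Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines high-stringency bacterial gene clusters into genus-level
    homologous groups using pairwise family-free DCJ-indel (double cut and
    join) distances. For every genome pair a gene similarity graph is built
    from normalized alignment bitscores, and an integer linear program
    jointly optimizes the gene matching, the number of adjacency-graph
    cycles, and indel (singleton/block) penalties; the resulting homology
    pairs merge scaffold clusters into refined groups, with paralog
    resolution into subgroups, core-genome extraction, and percentage of
    conserved proteins (POCP) genome-similarity summaries. Includes a
    synthetic genome/pangenome simulator with known truth for validation,
    readers for GFF3/FASTA annotations, tabular (BLAST outfmt 6 / m8)
    similarity hits and Roary-style cluster files, and a brute-force
    enumeration oracle for the distance model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
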
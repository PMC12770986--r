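Package: panfam
Title: Transparent Gene Clustering and Prokaryotic Pangenome Inference
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A transparent toolkit for prokaryotic pangenome analysis: parses
    annotated genomes (GFF3 with embedded FASTA), tags genes with their genome
    of origin, clusters them with a deterministic greedy incremental clusterer
    with CD-HIT-compatible parameter semantics (identity threshold c, length
    difference cutoff s), reads and writes CD-HIT .clstr files and edge lists,
    classifies gene families into user-definable presence bands (core,
    soft-core, shell, cloud), and emits Roary-style presence-absence matrices
    and summary statistics. A reclustering mode integrates newly annotated
    sequences into an existing pangenome while tracking how they extend, merge
    or fragment first-round families. Diagnostic utilities expose clustering
    fragility: per-cluster summaries, sequence lookup across outputs,
    run-to-run partition comparison, and normalised Robinson-Foulds
    concordance of single-gene trees. A synthetic pangenome generator with
    planted family structure supports end-to-end testing without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
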
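Package: minhashr
Title: Scaled MinHash Sketching, Indexing and Taxonomic Classification of Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build scaled (fractional) and bottom-n MinHash sketches of nucleotide
    and protein sequences, with optional k-mer abundance tracking. Sketches are
    persisted as human-readable JSON signatures and support set algebra
    (merge, intersect, subtract, flatten, downsample), Jaccard, containment and
    abundance-weighted cosine comparison, all-vs-all comparison matrices with
    clustered heatmap output, a Sequence Bloom Tree index with provably bounded
    similarity and containment search, a greedy best-first metagenome
    decomposition ('gather'), and an in-memory LCA database for k-mer based
    taxonomic classification and summarization. A deterministic synthetic-data
    generator makes every component testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
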
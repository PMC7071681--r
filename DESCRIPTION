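Package: kmerplex
Title: Barcode-Free Demultiplexing of Pooled Long Reads by Sample k-mer Indexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns each long read from a pooled (non-barcoded) sequencing run
    to its source isolate using per-sample k-mer indexes built from Illumina
    short-read data. For every sample a cleaned de Bruijn graph is represented
    as a canonical k-mer set: k-mers are counted from the short reads,
    partitioned into unitigs (maximal non-branching paths), and unitigs with
    low mean coverage are removed. Each long read is then assigned to the
    sample whose cleaned index contains the largest number of the read's
    k-mers, with seeded random tie-breaking. Includes the accompanying
    evaluation statistics (classification accuracy against a truth table,
    ends-free delta edit distance of mis-assigned reads, Phred-scaled QV
    conversion of SNP counts, k-mer survival model) and a simulator for
    synthetic bacterial communities, paired-end short reads and error-prone
    long reads, so the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    data.table,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
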
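Package: roast
Title: Reference-Free Optimization of Supertranscriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Iteratively detects and repairs errors in de novo
    supertranscriptome assemblies using only paired-end RNA-seq evidence.
    Alignment signatures (soft-clipped reads, reads with unmapped mates,
    read/mate islands on different contigs, and abrupt coverage breaks) are
    used to extend incomplete contigs, merge fragmented contigs, split false
    chimeras, and fix local mis-assemblies (missing sequence, unsupported
    insertions, translocations, inversions).  Includes a built-in
    seed-and-extend read aligner, a greedy overlap consensus assembler, a
    redundancy clusterer, and a benchmarking harness that generates synthetic
    supertranscriptomes, injects the seven canonical error types, simulates
    paired-end reads, and scores per-type recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rcpp,
    data.table,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
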
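Package: shufflonq
Title: Quantitative Structural Variation Analysis of Plasmid Shufflons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the rearrangement state of plasmid
    shufflons -- multiple DNA inversion systems in IncI-family conjugative
    plasmids whose invertible segments, bounded by short inverted repeats,
    are recombined by the Rci site-specific recombinase to vary the 3' end
    of the pilV gene.  The package enumerates the whole-shufflon arrangement
    space (2^n x n! states for n two-ORF segments), assigns spanning long
    reads to arrangements by BLASTN candidate search with collinear HSP
    chaining, types pilV variants from junction-containing reads on long- and
    short-read platforms, characterises inverted-repeat conservation
    (degenerate consensus, identity and Hamming matrices, SNV minimum
    spanning network), computes plasmid copy numbers from coverage, and
    classifies proper versus broken read pairs from alignments.  A seeded
    synthetic-data generator produces loci, heterogeneous arrangement
    populations and error-bearing long/short reads with ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
SystemRequirements: NCBI BLAST+ (blastn, makeblastdb) on the PATH for
    long-read arrangement assignment.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
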
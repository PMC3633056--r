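Package: asmmerge
Title: Reference-Free Merging of Draft Genome Assemblies Using Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Merges two draft genome assemblies (a trusted master and a
    secondary slave) without global alignment. Regions co-assembled by both
    assemblers are identified as blocks of uniquely aligned reads shared
    between the assemblies, organized into a weighted contigs graph and a
    directed assemblies graph. Order contradictions, putative inversions and
    mis-joins are detected from graph structure and arbitrated with
    paired-read evidence; validated junctions are confirmed by banded
    semi-global alignment and block regions are chosen by the CE insert-size
    statistic. The output is a conservatively merged assembly in which every
    ambiguous region falls back to the master sequence. Includes a synthetic
    fixture generator (genome, divergent assembly pair with engineered
    events, simulated read pairs, idealized alignments) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    GenomicAlignments,
    igraph,
    jsonlite,
    Rcpp,
    Rsamtools,
    stats
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
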
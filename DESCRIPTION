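Package: dusaGEI
Title: Detection and Excision Analysis of dusA-Associated Genomic Islands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery toolkit for integrase-bearing genomic islands that
    integrate into, and replace, the 5' end of the tRNA-dihydrouridine
    synthase gene dusA. Implements target-gene and divergent-integrase
    association screening with a tyrosine-recombinase catalytic-motif scan,
    seed-and-extend search for the semiconserved 21 bp attL/attR direct
    repeats bounding an island, island boundary calling, reconstruction of
    the excision products (circularized island carrying attP and the
    restored chromosome carrying attB) with restored-gene validation, in
    silico junction PCR, composition descriptors (GC content, trinucleotide
    atypicality), and a comparative layer (identity/similarity matrices,
    neighbour-joining trees with bootstrap support, attachment-site sequence
    logos, reciprocal-best-hit orthology with uniqueness and core-gene
    statistics). A seeded synthetic-genome generator implants islands with
    full ground truth so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
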
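Package: mtevo
Title: Mitochondrial Gene-Content Evolution, Genome Statistics, and
    Site-Rate Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the reductive evolution of organellar
    (chiefly mitochondrial) genomes on a known species phylogeny.
    Implements loss-only (Dollo) parsimony mapping of gene
    presence/absence repertoires onto a rooted tree (ancestral
    repertoires, per-branch loss events, parallel-loss census, and
    comparison of alternative rootings), Venn-style partitioning of gene
    repertoires by taxon-sharing pattern, annotated-genome summary
    statistics (composition, coding fraction, overlapping gene pairs,
    codon usage, tRNA wobble decoding coverage, nonstandard start
    codons), conditional-mean per-site evolutionary rate estimation
    under a discrete-gamma rates-across-sites model with progressive
    fast-site removal, bootstrap clade-support tabulation with a
    conflict screen against accepted taxonomic groups, and simulators
    that generate presence/absence matrices, amino-acid alignments, and
    annotated toy genomes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    IRanges,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
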
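Package: genopair
Title: Pairwise Intraspecies Genome Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome comparison of two closely related genome assemblies
    (e.g. two cultivars of the same crop species): a self-contained maximal
    exact match seeded, chained and banded-extended pairwise aligner with
    one-to-one and colinear block filters; sliding-window presence/absence
    variation (PAV) calling with cluster and PAV-gene assignment plus
    hypergeometric pathway enrichment; SNP and indel calling from alignment
    blocks with adjacent-indel merging, per-window densities and
    SNP-enrichment regions; inversion and translocation classification;
    k-mer based genome-size estimation and assembly Nx statistics;
    orthogroup duplication statistics; and coding-sequence/protein
    consequence calling with in-silico PCR. Includes a cultivar-pair
    simulator that plants SNPs (with density-enriched blocks), short indels,
    PAV segments, inversions and translocations while tracking exact truth
    coordinates in both genomes for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
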
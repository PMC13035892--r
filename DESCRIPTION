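Package: introgressr
Title: Competitive-Mapping Introgression Calling and Donor Assignment for
    Hybridizing Yeasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects interspecies introgressions at gene resolution from
    competitive-mapping depth profiles on a concatenated two-species
    reference (Saccharomyces cerevisiae x S. paradoxus), assembles
    introgressed genes into blocks, validates blocks phylogenetically
    against a small species panel, and assigns each block to its most
    likely donor lineage by identity-by-state. Includes the supporting
    population-genetic statistics (windowed nucleotide diversity and
    Tajima's D, per-strain heterozygosity, pairwise IBS, weighted
    Weir-Cockerham Fst, classical MDS, Spearman Mantel test),
    clade-level retention-pattern analysis with exact and permutation
    overlap tests, and a synthetic-data generator that emulates the
    full input bundle with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    geosphere,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    tibble,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
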
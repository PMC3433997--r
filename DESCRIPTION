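Package: beeroot
Title: SNP-Based Rooting Analyses for Honeybee Subspecies Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-genetic and phylogenetic analysis of diploid SNP
    genotype panels structured into subspecies and lineage groups, built for
    interrogating the geographic origin of the Western honeybee (Apis
    mellifera). Provides polymorphism-sharing tabulations (polymorphic,
    private and fixed private loci per subspecies and lineage group),
    sample-size-corrected Watterson's theta, Weir-Cockerham F_ST and
    allele-sharing distances, a deterministic neighbor-joining implementation
    with locus-bootstrap resampling, majority-rule consensus and
    split-compatibility filtering, categorical classification of outgroup
    placement across bootstrap replicates, taxon-exclusion robustness
    analyses, NeighborNet split networks with non-negatively constrained
    split weights, and a Balding-Nichols-style synthetic panel generator
    with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
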
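Package: strpopgen
Title: Forensic STR Population Genetics at Length and Sequence Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for forensic short-tandem-repeat (STR) population data at
    both capillary-electrophoresis (length) and massively-parallel-sequencing
    (sequence) resolution. Parses bracket-notation repeat structures and maps
    them to CE allele designations; estimates allele and Y-haplotype
    frequencies by direct counting; computes the standard per-locus forensic
    parameter suite (observed/expected heterozygosity, PIC, match probability,
    power of discrimination, power of exclusion, typical paternity index) with
    combined multi-locus powers, and exact Hardy-Weinberg tests with
    Bonferroni correction; summarises Y-STR haplotype diversity, match
    probability and discrimination capacity, including marker-kit comparison;
    builds pairwise Fst (Weir-Cockerham) and Rst (repeat-count variance)
    distance matrices between populations and analyses them by classical
    multidimensional scaling and neighbour-joining trees with Newick output.
    Includes a synthetic-population generator (Dirichlet allele frequencies,
    iso-length sequence variants, founder-lineage Y haplotypes,
    Balding-Nichols divergence) so every stage is testable without access to
    casework genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
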
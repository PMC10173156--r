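Package: polycore
Title: Dosage-Based Curation of Polyploid Genebank Collections
Version: 0.1.0
Authors@R: person("AGROSAVIA", "Bioinformatics", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for curating clonal genebank collections genotyped with
    biallelic SNP allele-dosage calls on the tetraploid scale (0-4): quality
    filtering by minor allele frequency and missingness, per-sample ploidy
    inference from the frequency of simplex and triplex dosage calls,
    dosage-based diversity statistics (observed heterozygosity, Modified
    Rogers distances, Nei-style FST, distance-based AMOVA with permutation
    tests), population structure via PCA and k-means with clustering-index
    selection of the number of groups, genetic-distance-optimized core and
    mini-core collection selection under the accession-to-nearest-entry
    objective, phenotypic validation with Gower distances, and a seeded
    mixed-ploidy panel simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    VariantAnnotation,
    yaml,
    optparse
Config/testthat/edition: 3
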
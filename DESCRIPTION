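Package: mkregmap
Title: Megakaryocyte Regulatory Landscapes and Variant-to-Gene Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Links non-coding GWAS variants for platelet traits to candidate
    target genes through megakaryocyte and erythroblast regulatory landscapes.
    Provides interval algebra over 0-based half-open genomic coordinates,
    classification of open-chromatin peaks by their opening dynamics across
    haematopoietic differentiation, super-enhancer calling by H3K27ac
    stitching and rank-curve thresholding, promoter-capture Hi-C based
    region-to-gene mapping, a tiered variant-to-gene assignment algorithm with
    a linkage-disequilibrium proxy cascade and a bait-proximity fallback, and
    a circular genomic permutation enrichment test. A deterministic synthetic
    study generator emulates the data structures of such a study so the whole
    pipeline runs and is tested at desk scale without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
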
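Package: merfishniche
Title: MERFISH Spatial Niche Analysis of Densely Packed Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for multiplexed error-robust
    fluorescence in situ hybridization (MERFISH) data from densely packed
    tissue such as fetal liver: construction of the 16-bit Hamming-distance-4
    barcode codebook, fiducial-bead drift correction, pixel-based barcode
    decoding, watershed cell segmentation on a membrane stain, cell- and
    gene-level quality control, Louvain-Jaccard clustering and marker-based
    cell typing, percentile-based stem-cell calling, spatial cell-type
    pair-proximity enrichment against a random-pairing null, stem-cell niche
    definition and composition testing, replicate-reproducible differential
    expression, and a niche gene to cell-type-marker co-expression screen.
    A synthetic tissue-scene generator with known ground truth (cell
    positions, types with spatial affinity, counts, and rendered images)
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    EBImage,
    class
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
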
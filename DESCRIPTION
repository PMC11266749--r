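Package: granulefish
Title: Quantification of Single-Molecule FISH Spots, Clusters and
    Germ-Granule Enrichment in Early Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for quantifying single-molecule
    fluorescence in situ hybridization (smFISH) images of early
    C. elegans embryos: 3D spot detection with iterative Gaussian-mask
    sub-pixel localization, single-molecule intensity calibration from
    somatic blastomeres, molecule-count binning and cluster calling,
    maximum-entropy (Kapur) thresholding plus watershed segmentation of
    germ granules, bounding-cube spot/granule and cluster/cluster
    colocalization, P-blastomere concentration-enrichment metrics, and
    Group I/II/III classification of screen annotation tables. Includes
    a synthetic-embryo generator with exhaustive ground truth (PSF
    rendering, multi-molecule clusters, ellipsoidal granules,
    asymmetric-lineage partitioning, Poisson and read noise) so every
    stage can be validated against a known answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
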
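Package: fundusreg
Title: Retinal Fundus Image Registration via Vascular Graph Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Feature-based registration of retinal fundus image pairs.
    Vessel centerlines are enhanced with oriented second-order
    Gaussian-Hermite matched filters, segmented by threshold probing,
    thinned to one-pixel skeletons and abstracted into attributed
    vascular structure graphs whose edges carry normalized vessel-path
    and Euclidean distances. Global bifurcation correspondences are
    found by graduated-assignment graph matching on a bistochastically
    normalized edge-compatibility matrix, purged of wrong matches by a
    deterministic structure-based sample consensus (STRUCT-SAC), and
    refined with an iterative-closest-point stage under a 12-parameter
    quadratic transformation model. Registration quality is reported as
    the vessel centerline error measure (CEM), normalized correlation
    and normalized mutual information. A synthetic vascular phantom
    generator with ground-truth warps and node correspondences supports
    validation at every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, EBImage, Matrix, data.table, jsonlite, yaml
Suggests: testthat (>= 3.0.0), vegan
biocViews: Visualization, Alignment
Config/testthat/edition: 3
RoxygenNote: 7.3.3
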
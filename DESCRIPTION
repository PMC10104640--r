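Package: vasq
Title: Quantitative Mapping of Intravascular Drug Release in Vascularized
    Tissue Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Semiautomated analysis of bright-field and fluorescent
    microscopy images of drug-containing vascular networks. Provides vessel
    segmentation (a dual-attention U-Net trained adversarially, plus a
    classical thresholding fallback), two-subiteration thinning to a
    single-pixel skeleton, graph-based branch classification into five
    hierarchical levels, intravascular drug-concentration mapping through a
    modified Beer-Lambert attenuation model, extravascular diffusion-depth
    and coverage metrics, and in vitro-in vivo correlation fitting. A
    synthetic vascular-phantom generator with full ground truth makes every
    stage testable without experimental images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    igraph,
    jsonlite,
    yaml,
    png,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'vasq-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'augment.R'
    'classical.R'
    'diffusion.R'
    'io.R'
    'metrics.R'
    'nn.R'
    'phantom.R'
    'photometry.R'
    'pipeline.R'
    'skeleton.R'
    'topology.R'
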
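Package: gliotopo
Title: Connectomic, Cellular and Transcriptomic Correlates of Glioma Topography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing why gliomas localize non-randomly across the
    brain. Builds voxel-wise tumour frequency maps from cohorts of binary
    lesion masks, aggregates them onto a symmetric parcellation, and relates
    regional tumour frequency to functional-connectome hub metrics,
    stem/progenitor-cell marker enrichment, and regional gene expression via
    partial least squares with bootstrap gene ranking. Inference for
    map-to-map correspondence uses spatial-permutation ("spin") null models
    that preserve spatial autocorrelation, with Moran's I diagnostics. An
    integrative regression decomposes tumour frequency variance into
    connectomic, cellular and transcriptomic contributions. A synthetic-data
    generator with planted effect sizes emulates the statistical structure of
    the required imaging, connectome and expression inputs so that the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    rlang,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
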
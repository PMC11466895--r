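Package: gaussflex
Title: Continuous Conformational Heterogeneity in Cryo-EM via Gaussian
    Pseudo-Atom Deformation Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-particle continuous conformational deformations
    of a Gaussian pseudo-atom consensus model from cryo-EM particle images.
    Two variational autoencoders are trained independently on gold-standard
    half sets; a coordinate-based decoder with positional encoding outputs a
    3D deformation field per particle, regularized by local-isometry and
    repulsion penalties on a nearest-neighbour graph. Learned deformations
    are inverted with a regression network and used in deformed weighted
    backprojection to produce improved half-maps, and decoder disagreement
    on a held-out validation subset yields per-particle deformation error
    estimates. Includes readers and writers for MRC/MRCS volumes and stacks,
    RELION-style STAR particle metadata and PDB atomic models, a CTF and
    Fourier-space image-formation model, and a synthetic-data simulator with
    known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
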
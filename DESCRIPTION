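Package: ilamhc
Title: Pan-Specific Peptide-MHC Class I Binding Prediction with
    Convolutional Networks on Image-Like Contact Encodings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes nonapeptide-HLA class I binding pairs as multi-channel
    image-like arrays built from amino-acid physicochemical properties at
    the 34 NetMHCpan-style contact residues, trains a small deep
    convolutional network as a pan-specific binder/non-binder classifier
    (IC50 < 500 nM rule), evaluates it with an F1 benchmark protocol over
    reference/allele/measurement-type subsets, and explains individual
    predictions with DeepLIFT-style signed informative-pixel maps. Includes
    a synthetic data generator with planted anchor-position and pairwise
    synergy energetics so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
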
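Package: MatrixPalette
Type: Package
Title: Substitution-Matrix-Derived Color Schemes for Sequence Alignment
    Visualization
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generates color schemes for sequence-alignment visualization
    directly from a substitution matrix. Each alphabet symbol is assigned a
    point in CIE L*a*b* color space such that pairwise perceptual color
    differences (CIEDE2000) are proportional to pairwise evolutionary
    distances derived from the matrix. Optimal color conformations are found
    by an ensemble of simulated-annealing optimizers over a user-constrained,
    displayable region of color space, with a random-sampling baseline and
    Z-score diagnostic to assess optimizer quality. Schemes are exported as
    JSON maps from symbol to sRGB hex color.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, jsonlite, optparse, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), Biostrings, grDevices
Config/testthat/edition: 3
RoxygenNote: 7.3.3
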
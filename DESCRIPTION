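Package: quantphylo
Title: Quantitative Protein Phylogeny from Physico-Chemical Sequence Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts aligned protein sequences into numeric profiles of measured
    amino-acid physico-chemical properties (volume, hydropathy, solubility,
    transfer free energies, isoelectric point and more, with alignment gaps
    encoded as 0) and analyses the resulting number strings with tools from
    complex-systems research: agglomerative sum-difference (L1) phylogenetic
    trees with position-wise profile averaging, pairwise relatedness by
    correlation, average mutual information and box-counting dimension
    aggregated across properties, and bivariate Morlet wavelet analysis
    (cross-power, coherence, phase difference, surrogate significance) to
    localize conserved versus hypermutable protein regions. Includes a
    consensus-sequence builder, a synthetic protein-family simulator with
    planted phylogenies for validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    seqinr,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
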
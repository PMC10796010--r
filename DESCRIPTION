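Package: histonefold
Title: Order Parameters, Free-Energy Reconstruction and Sequence Symmetry
    for Histone Dimer Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis toolkit for studying the folding of
    histone and histone-like dimers at the C-alpha level: the
    native-contact order parameter Q (monomer, dimer and interface
    variants) and the fraction of native contacts, Kabsch superposition
    with RMSD/RMSF and pairwise-RMSD conformational clustering,
    helix-axis fitting and the alpha2-alpha2 inter-helix crossing angle
    that separates native from inverted (non-native) handshake dimers,
    weighted histogram analysis (WHAM) reconstruction of 1D free-energy
    profiles from umbrella-sampled windows with reweighting onto 2D
    surfaces, radius-of-gyration polymer scaling fits, and a
    reversed-sequence hydrophobic-symmetry statistic with a permutation
    null.  A synthetic-data module generates every input with known
    ground truth: ideal helices and two-helix dimers at a prescribed
    crossing angle, noisy conformational ensembles, Metropolis samples
    from analytic potentials under harmonic umbrella biases, and
    sequence pairs with planted head-tail hydrophobic symmetry.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
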
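Package: idpens
Title: Integrative Conformational Ensembles for Intrinsically Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determination and comparison of conformational ensembles for
    intrinsically disordered proteins from heterogeneous biophysical data.
    Generates contrasting prior conformer pools by statistical-coil chain
    growth, back-calculates SAXS, chemical-shift, FRET and PRE observables
    with simplified forward models, optimizes ensembles either by Bayesian
    Maximum Entropy reweighting (with a composite chi-squared objective,
    theta scanning, L-curve elbow selection and held-out PRE validation) or
    by switching Monte-Carlo subset selection under simulated annealing with
    target-normalized pseudo-energies, and compares the resulting posteriors
    through weighted structural analytics: secondary-structure propensities,
    inter-residue scaling maps, hydrogen-bond probability mass functions,
    planar pi-contact counts and weighted-bootstrap uncertainties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
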
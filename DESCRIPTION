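Package: cpnano
Title: Stability Analysis of Cyclic Peptide-Polymer Nanotubes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse the stacking stability of cyclic D,L-peptide
    nanotubes. Builds idealized antiparallel-stacked nanotube models with a
    known backbone hydrogen-bond network, generates synthetic trajectories
    and two-state Markov bond dynamics with known ground truth, detects
    backbone hydrogen bonds geometrically with interface-resolved cap/core
    classification, computes broken-hydrogen-bonds-per-nanosecond stability
    statistics and cap-dissociation events, summarizes nanotube length
    distributions, and fits the orientation-averaged core-shell cylinder
    small-angle-scattering model to 1-D intensity curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
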
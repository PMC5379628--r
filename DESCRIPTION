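Package: gatekin
Title: Single-Channel Gating Kinetics and Pore Geometry of Tetrameric Ion Channels
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the kinetic and structural characterization of
    tetrameric cation channels such as TRPV5. Provides continuous-time
    Markov models of single-channel gating (the linear O <-> C2 <-> C1
    scheme with a pre-open closed state), exact stochastic simulation and
    rendering of patch-clamp current traces, half-amplitude idealization
    with dead-time imposition, maximum-likelihood fitting of left-truncated
    exponential dwell-time mixtures and of the full three-state model
    (open probability, time constants, closing rate constant), amplitude
    histogram analysis by Gaussian mixtures, whole-cell I-V curve
    processing (percent-of-maximum normalization, EGTA-sensitive currents,
    current densities), and pore geometry of tetrameric structures:
    HOLE-style pore radius profiles by inscribed-sphere optimization,
    symmetric side-chain rotamer manipulation, inter-subunit gate
    apertures, and ion permeation feasibility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    bio3d,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'gatekin-package.R'
    'idealize.R'
    'io.R'
    'kinetics.R'
    'markov.R'
    'pore.R'
    'rotamer.R'
    'toypore.R'
    'wholecell.R'
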
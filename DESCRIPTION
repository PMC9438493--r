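Package: dmphase
Title: Ab Initio Phasing of High-Solvent-Content Protein Crystals by Iterative Projection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Direct (ab initio) determination of crystallographic phases for
    protein crystals with high solvent content, using iterative projection
    algorithms. Implements the Difference Map and Error Reduction update rules
    with solvent-flatness and histogram-matching constraints in real space and
    a Fourier-amplitude constraint with a Wilson-statistics guard on missing
    data; Gaussian apodization with equal-area resolution-extension schedules;
    variance-based molecular-envelope determination with a triweight filter;
    origin and inversion registration; density-based clustering of envelopes
    and phase sets with consensus averaging; and a synthetic toy-crystal
    generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'unitcell.R'
    'spacegroup.R'
    'densitymap.R'
    'apodization.R'
    'reflections.R'
    'map-io.R'
    'fourier-proj.R'
    'real-proj.R'
    'dm-engine.R'
    'registration.R'
    'clustering.R'
    'protocols.R'
    'synthetic.R'
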
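Package: abfekit
Title: Automated Construction and Estimation of Absolute Binding Free Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational core of an automated absolute binding free energy
    (ABFE) workflow for protein-ligand complexes. Constructs the anchor-atom
    and dummy-particle restraint frame from aligned structures, assigns
    translational/rotational and conformational harmonic restraints, schedules
    attachment windows, estimates free-energy components with MBAR or
    thermodynamic integration with Gaussian quadrature, evaluates the
    semi-analytic standard-state release term for the orientational
    restraints, assembles double-decoupling (DD) and simultaneous
    decoupling-recoupling (SDR) thermodynamic cycles, and combines multiple
    docked poses by Boltzmann weighting. Molecular-dynamics sampling is
    replaced by a pluggable per-window sample interface together with a
    synthetic Boltzmann sampler with closed-form reference free energies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
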
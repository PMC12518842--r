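Package: igdyn
Title: Antibody Fragment Dynamics from Neutron Spin-Echo, SAXS, DLS and
    PFG-NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained modelling and analysis of immunoglobulin (IgG)
    fragment dynamics in crowded solution. Builds residue-level bead models
    of the Y-shaped antibody with internal displacement modes ("attack"
    stretching, in-/out-of-plane "search" bending, axial fragment rotation),
    computes static form factors, scattering-amplitude asymmetry and
    colloidal structure factors (Percus-Yevick, rescaled MSA), coherent mode
    form factors and composite neutron spin-echo intermediate scattering
    functions, Ornstein-Uhlenbeck models of harmonically bound fragment
    motion, rigid-body bead-model diffusion tensors, a delta-gamma-type
    hydrodynamic function linking collective, short-time and long-time
    self-diffusion, and seeded synthetic-data generators with known ground
    truth for SAXS, NSE, DLS and PFG-NMR observables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
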
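Package: janusdpd
Title: Dissipative Particle Dynamics of Janus Nanoparticles at Lipid Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale dissipative particle dynamics (DPD) simulator and
    analysis pipeline for amphiphilic Janus nanoparticles interacting with
    DPPC lipid monolayers at the air-water interface. Includes builders for
    cubic-lattice Janus nanoparticles, 14-bead DPPC lipids and double-monolayer
    water-slab systems; a momentum-conserving DPD engine with an exponential
    gas-bead force for quantitative gas-liquid interfaces, harmonic bonded
    terms, smeared-charge electrostatics, a Berendsen barostat and a virial
    pressure tensor; and observables for nanoparticle orientation, surface
    tension and surface pressure, lipid tail order and liquid-condensed
    fraction, effective area per lipid, and a contact-energy based surface
    energy decomposition of the nanoparticle-monolayer system.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
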
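Package: redoxpot
Title: Reduction Potentials of Redox Proteins from Continuum Electrostatics
Version: 0.1.0
Authors@R:
    person("redoxpot", "developers", email = "redoxpot@example.org",
           role = c("aut", "cre"))
Description: Computes standard reduction potentials of redox-site-containing
    proteins from structure. The intrinsic reduction free energy of the
    cofactor is taken from a parameter library, while the environmental
    contribution of protein plus solvent is obtained from a built-in
    finite-difference linear Poisson-Boltzmann solver through a four-state
    thermodynamic cycle. Includes structure preparation (segment
    partitioning, hydrogen building, protonation edits, charge knock-outs,
    truncation mutations), analytic Born and Kirkwood validation fixtures,
    and per-residue contribution analysis for identifying sequence
    determinants of the reduction potential.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
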
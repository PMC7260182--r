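Package: celiris
Title: Conformational Energy Landscapes and Infrared Ion Spectra of Glycosyl Cations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for mapping the conformational energy landscape (CEL) of
    six-membered-ring glycosyl cations and for simulating and assigning their
    infrared ion spectra. Implements Cremer-Pople ring-puckering analysis with
    canonical conformer classification, enumeration of a dihedral-constrained
    conformational grid with acyl-rotamer (R1/R2) comparison, quasi-harmonic
    thermochemistry and Boltzmann ensemble weighting, sphere-slice free-energy
    heat maps with local-minimum detection, and a staged infrared spectrum
    pipeline (distance-geometry conformer search, diversity and energy
    filtering, frequency scaling, Gaussian broadening, spectral matching, and
    diagnostic-band classification of oxocarbenium, dioxolenium, and
    ring-opened ions). Electronic-structure energies and frequencies are
    consumed through a pluggable backend contract with analytic toy and
    classical valence-forcefield backends and a file adapter for external
    quantum-chemistry programs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
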
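Package: glassrelax
Title: Molecular Mobility and Crystallization Stability Analysis for
    Pharmaceutical Glasses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of the molecular mobility and physical stability of
    amorphous drugs and amorphous solid dispersions.  Deconvolutes broadband
    dielectric loss spectra into Havriliak-Negami and Cole-Cole relaxation
    modes, builds relaxation maps with Arrhenius and Vogel-Fulcher-Tammann
    fits, extracts the Kohlrausch-Williams-Watts stretching exponent from the
    alpha-peak shape, and predicts Johari-Goldstein relaxation times with the
    Coupling Model.  Calorimetric tools cover glass-transition detection,
    Donth cooperatively-rearranging-region sizing, enthalpy-recovery KWW
    fitting, cold-crystallization features, two-Lorentzian melting-peak
    deconvolution for polymorph fractions, and remaining-glass-fraction
    tracking.  Crystal nucleation assays and polarized-light-microscopy
    growth tracks are summarized with binomial and mixture statistics.
    Seeded synthetic-data generators emulate every supported input with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    mclust,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
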
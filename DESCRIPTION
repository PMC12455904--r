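Package: srtriplex
Title: Triple-Energy Photon-Counting Simulation for Bone-Strontium Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and precision-analysis framework for triple-energy
    photon-counting x-ray quantification of strontium in bone. Provides
    parametric mass-attenuation curves with K-edge handling, filtered anode
    spectra (W/Ag, Rh/Rh, Mo/Mo at 20-50 kVp), a three-phalanx finger phantom
    with projected areal densities, an energy-bin response model for a CdTe
    photon-counting detector with analog charge summing and Gaussian
    electronic noise, a linearized forward count model, generalized
    least-squares precision bounds for the strontium-to-bone concentration,
    limit-of-quantification and minimum-dose metrics, first-order dosimetry,
    exhaustive acquisition-parameter optimization, and a per-bin projected
    Fisher-information decomposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
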
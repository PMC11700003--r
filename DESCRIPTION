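Package: ccbrachy
Title: Collapsed-Cone Successive-Scattering Dose Engine for HDR Ir-192
    Brachytherapy
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A voxel-based collapsed-cone point-kernel superposition dose
    engine for high-dose-rate Ir-192 brachytherapy that computes the total
    dose separated by photon scatter generation into primary, first-scatter
    and multiple-scatter components on heterogeneous phantoms. The
    multiple-scatter line transport is available in two modes: the original
    water-kernel transport with attenuation scaling only, and a corrected
    transport that adds a spectrum-averaged linear energy-absorption scaling
    factor together with a compensating transported-energy correction, so
    that local absorption changes in non-water media are balanced by the
    energy carried onward along each transport line. The package ships a
    generation-resolved photon-only Monte Carlo reference with collision
    kerma scoring and scatter-generation bookkeeping, forced-interaction
    kernel generation with bi-exponential kernel fitting, benchmark phantom
    builders (a cubic water phantom with a box heterogeneity of cortical
    bone or air), and a comparison layer producing percentage dose
    difference ratio maps, region statistics, histograms and profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
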
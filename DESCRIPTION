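Package: isoflux
Title: Isotope-Resolved Vibrational Spectroscopy Chemometrics for Microbial Carbon Flux
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for tracking 12C/13C carbon flux into microbial metabolites with
    multimodal vibrational spectroscopy. Simulates isotope-shifted FTIR and Raman
    spectra and hyperspectral images of oleaginous fungal biomass with known ground
    truth, applies standard chemometric preprocessing recipes (Savitzky-Golay
    derivatives, rubberband and polynomial baselines, MSC/EMSC, normalisations,
    cosmic-ray removal), quantifies metabolite trajectories from isotope-resolved
    marker bands, and provides principal component analysis, multiblock consensus
    PCA with correlation loadings, PLS regression with prediction-residual
    reliability flags, and hyperspectral image quality control, binning and
    non-negative basis-spectrum unmixing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
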
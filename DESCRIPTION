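Package: cavechron
Title: Multi-Method Geochronology, Dental Morphometrics and Enamel
    Proteomics for Cave Fossil Assemblages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dating and analysing hominin fossils from karstic
    sites. Implements closed-form 230Th/U carbonate ages with detrital
    thorium correction and isochron intercept fitting; coupled
    uranium-series and electron spin resonance (US-ESR) dating of dental
    tissues with an open-system uranium-uptake model; luminescence central
    and minimum age models, anomalous-fading (g-value) correction and
    dose-rate assembly; a Bayesian ordered-sequence stratigraphic age
    model with phase boundaries sampled by MCMC; crown metric comparison
    via adjusted Z-scores and 3D tissue proportions; enamel-dentine
    junction semilandmark geometric morphometrics (Procrustes, PCA,
    between-group PCA, CVA, cross-validation); and screening of ancient
    enamel peptide-spectrum matches (PTM spectral counting, phospho-motif
    tallies, diagnostic-site coverage, amelogenin-Y sex screening).
    Seeded synthetic-data generators make every analysis testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    numDeriv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
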
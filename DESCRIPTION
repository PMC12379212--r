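Package: neolexp
Title: Demic and Cultural Diffusion Models of the European Neolithic Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models of the spread of farming and Early Farmer (EF) genetic
    ancestry across a hunter-gatherer Europe. Implements a one-dimensional
    three-population reaction-diffusion model with cultural transmission, a
    two-dimensional spatial agent-based simulation with overlapping
    generations, age- and density-dependent mortality, within-group mating
    and horizontal learning with diploid marker genomes, plus the summary
    statistics (front speed, cultural effect, ancestry clines) and the
    Gaussian measurement-error profile-likelihood machinery used to estimate
    the learning rate and within-group mating probability from ancient-DNA
    ancestry point estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    Rcpp,
    MASS,
    geosphere,
    yaml,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
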
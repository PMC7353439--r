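Package: shrinkcore
Title: Shrinking-Core Analysis of Copper Ion Release from Biocidal
    Nanoparticles and Modified Membranes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the dissolution of biocidal copper species (Cu and CuO
    nanoparticles in suspension, copper complexed in thin-film-composite
    membranes) with the shrinking core model. Provides the three
    single-resistance conversion laws and their characteristic times, a
    mixed-control quasi-steady oracle, rate-limiting-step determination by
    through-origin linearization scored with adjusted R-squared, nonlinear
    least-squares estimation of effective diffusivity and apparent particle
    number (and a Nernst-Brunner first-order variant for membrane-complexed
    copper) with confidence intervals, the bacterial growth-inhibition
    indicator from CFU curves, and seeded synthetic-data generators so the
    whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
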
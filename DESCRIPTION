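Package: gelpen
Title: Particle Penetration into Swollen Biological Polymer Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Microscopically motivated modelling of micro- and nanoparticle
    penetration into swollen biological gels such as mucus and bacterial
    biofilms. Implements freely-jointed-chain entropic elasticity with the
    rational inverse-Langevin approximant, a geometric criterion for
    spontaneous (unforced) particle penetration that turns reported
    penetrating-particle diameters into mesh-size and chain-length
    estimates, and a quasi-static simulator of forced penetration of
    spherical and ellipsoidal particles into a locally quadrilateral chain
    lattice, including chain-rupture and cross-link-dissociation damage
    criteria. Functions take data frames and return tibbles; results carry
    tidy() and glance() methods and ggplot2 autoplot() visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
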
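Package: selfersim
Title: Accumulation of Genetic Incompatibilities Under Partial Self-Fertilisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models of how underdominant, compensatory and
    Bateson-Dobzhansky-Muller incompatibility mutations accumulate in a
    single partially selfing population. Provides exact one-generation
    deterministic recursions for the ten two-locus genotype classes under
    meiosis, partial selfing, irreversible mutation and selection;
    diffusion-based fixation probabilities and fixation-time
    decompositions with closed-form and quadrature evaluation; stochastic
    Wright-Fisher simulators (single-locus, two-locus genotype-class and
    individual-based multilocus engines, with multinomial or
    Dirichlet-multinomial drift to emulate background selection); a
    gamma-distributed spectrum of underdominant effects; right-censored
    gamma mean correction for fixation-time summaries; and preset
    experiment grids with analytic predictions joined to simulation
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    fitdistrplus
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
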
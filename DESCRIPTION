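Package: evorescue
Title: Individual-Based Simulation of Evolutionary Rescue Under Density
    Dependence and Genetic Erosion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Stochastic individual-based simulation of evolutionary rescue in
    diploid populations with a finite-locus quantitative trait under Gaussian
    stabilizing selection and Ricker (exponential) negative density
    dependence. Provides the one-generation life cycle (phenotype expression,
    intrinsic fitness, density-regulated Poisson reproduction with Mendelian
    segregation and random mating), factorial simulation experiments over
    density dependence, founding size and standing genetic diversity,
    classification of extinction and of fitness- and size-based rescue, a
    constant-genetic-variance analytic reference model with a Ricker term,
    reversed-time extinction-vortex statistics, and logistic-regression effect
    sizes of treatments and initial maladaptation on population fates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
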
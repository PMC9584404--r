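Package: leptoflow
Title: Biophysical Larval Dispersal Simulation and Connectivity Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based Lagrangian simulation of leptocephalus larval
    dispersal through gridded 4-D ocean fields, with thermocline-relative
    spawning releases, ontogenetic buoyancy, diel vertical migration,
    thermal and onshore mortality, and settlement-zone recruitment.
    Includes an analytic synthetic-ocean generator (stratified columns,
    gyres, boundary currents, coastlines), stochastic random-walk
    dispersion scaled by Okubo's empirical diffusivity law, and the
    downstream assessment layer: fate bookkeeping, gridded densities,
    settlement kernel density estimates, island connectivity matrices and
    settlement footprints, coefficient of dispersal, and nonparametric
    island contrasts (Kruskal-Wallis, Dunn's test with Bonferroni
    correction, Hedges' g with bootstrap confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    MASS,
    nortest,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
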
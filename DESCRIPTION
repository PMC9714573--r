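Package: pnnbrush
Title: Coarse-Grained Langevin Dynamics of Diffusion in Charged Polymer Brushes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bead-spring Langevin dynamics of a planar polyelectrolyte brush --
    a simplified model of the perineuronal net -- with a single diffusing tracer.
    Implements the truncated Lennard-Jones, harmonic bond, harmonic bend and
    Debye-Hueckel screened-Coulomb force field with periodic boundaries and
    cell-list acceleration; a BAOAB Langevin integrator; anisotropic diffusion
    constant estimation from dual mean-square-displacement curves with
    group-wise errors; brush-structure observables (radius of gyration, brush
    height, correlation length, persistence length, energy bookkeeping);
    porosity/tortuosity effective-diffusion model fitting including a
    generalized random-walk tortuosity model; and a Nernst-Einstein
    conductivity and spherical-shell resistance endpoint. Synthetic trajectory
    generators (anisotropic Brownian walkers, velocity Ornstein-Uhlenbeck
    crossover processes, discrete worm-like chains) make every analysis stage
    testable without running molecular dynamics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
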
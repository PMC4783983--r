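Package: solvdyn
Title: Trajectory Analysis of Solvent-Controlled Protein Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for molecular dynamics trajectories of
    protein-solvent systems simulated with the solute and solvent coupled
    to different temperatures. Implements essential dynamics (principal
    component analysis of atomic-fluctuation covariance), combined
    essential dynamics for comparing two simulations, cosine-content
    convergence diagnostics, static/dynamic hydrogen-bond bookkeeping with
    persistency and class breakdowns, per-residue RMSF and burial-depth
    flexibility profiles, structural property tables (RMSD, radius of
    gyration, native contacts, solvent accessible surface area, secondary
    structure) with percent- and fold-change arithmetic, solvent
    mean-square displacement with hydration-shell classification, and
    free-energy landscapes from Boltzmann histogram inversion or a toy
    overdamped-Langevin well-tempered metadynamics engine on analytic
    collective variables. Ships synthetic-trajectory generators with
    planted ground truth (covariance modes, hydrogen-bond schedules,
    two-state hopping, diffusing or arrested solvent) so every analysis
    stage can be validated against a known answer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
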
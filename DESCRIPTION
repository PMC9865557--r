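Package: ilscale
Title: Charge and van der Waals Scaling Toolkit for Fixed-Charge Ionic-Liquid Force Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tuning and evaluating fixed-charge force fields for
    ionic liquids. Reads and writes a GROMACS-dialect topology subset and
    applies uniform atomic-charge and Lennard-Jones sigma scaling; scores
    point-charge quality by relative root-mean-squared error of the
    reproduced electrostatic potential on molecular grids; estimates
    solvation and water-to-ionic-liquid transfer free energies from
    nonequilibrium (fast-growth) work distributions with the Jarzynski
    exponential-averaging estimator and bootstrap uncertainties; computes
    experiment-calculation quality metrics (MAE, MSE, RMSE, Kendall tau,
    Pearlman predictive index, Pearson r, outlier counts); fits the linear
    density response to scaling factors and recommends density-matched and
    balanced scaling factors. A desk-scale NPT Metropolis Monte Carlo ionic
    soft-sphere fluid and a Crooks-consistent Gaussian work generator
    provide self-contained test beds for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, pracma
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
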
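Package: solvshell
Title: Solvation-Shell-Resolved Structure Analysis for Aqueous Electrolytes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for dissecting the microscopic structure of liquids and
    electrolyte solutions from particle trajectories: partial radial
    distribution functions and O-O-O angular distributions, Faber-Ziman
    partial and neutron-weighted composite structure factors, assignment of
    water molecules to ionic first solvation shells, excluded-volume
    corrected "free water" correlation functions, virtual diffraction over
    atom subsets, and geometric hydrogen-bond network statistics including
    hydrogen-bond chains.  Ships a synthetic-data module (ideal gases,
    diamond-cubic tetrahedral networks, soft-sphere Monte Carlo
    electrolytes) so every analysis can be exercised and validated against
    analytic geometry without external simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
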
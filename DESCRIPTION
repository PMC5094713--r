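Package: enzcost
Title: Enzyme Cost Minimization for Metabolic Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the metabolite and enzyme concentration profiles that
    realize a given metabolic flux distribution at minimal total enzyme cost.
    Enzyme demand is written as a function of metabolite log-concentrations
    through separable (factorized) reversible rate laws, turning enzyme cost
    minimization into a convex program over the thermodynamically feasible
    metabolite polytope. Includes a tiered family of enzyme cost functions
    ranging from sum-of-fluxes to full modular rate laws, a max-min driving
    force (MDF) linear-programming baseline, Haldane-consistent kinetic
    parameter balancing, tolerance ranges for nearly optimal states,
    Monte-Carlo sensitivity analysis, cost-optimality testing against
    measured enzyme levels, and readers/writers for SBtab-style TSV model
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
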
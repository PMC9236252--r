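Package: tyrcycle
Title: Mechanistic Modelling of the Microtubule Detyrosination/Tyrosination Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemical-reaction-network model of the microtubule
    detyrosination/tyrosination cycle (soluble tubulin and microtubule pools in
    tyrosinated and detyrosinated form, regulated by the TTL and TCP enzymes),
    with neuronal and proliferative parameterizations. Provides stiff ODE
    simulation with event-based parameter perturbations and steady-state
    detection, a quantitative temporal-logic layer that scores simulation
    traces against behavioural specifications with a continuous satisfaction
    degree, CMA-ES parameter search (single-parameter and all-pairs sweeps,
    minimal-change fitting, satisfaction-degree landscapes), Monte-Carlo
    robustness analysis of the equilibrium tyrosination status, a structural
    multistationarity check based on positive circuits in the labelled
    influence graph, a synthetic high-content-imaging generator for single-cell
    intensity tables with Z'-factor assay scoring, and SBML/CSV/config I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
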
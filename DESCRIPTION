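Package: alzsim
Title: Mechanistic Simulation of Alzheimer's Disease Progression and In
    Silico Drug Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an eighteen-species mechanistic network model of
    Alzheimer's disease progression coupling amyloid-beta pools,
    hyperphosphorylated tau and neurofibrillary tangles, live and dead
    neurons, astrocytes, pro- and anti-inflammatory microglia and
    peripheral macrophages, and the cytokines TNF-alpha, TGF-beta, IL-10
    and MCP-1.  Provides a well-mixed stiff ODE mode and a 2-D periodic
    reaction-diffusion-chemotaxis mode, in silico trials of TNF-alpha
    inhibition, TGF-beta injection, anti-amyloid antibody, MCP-1
    inhibition and tau-aggregation inhibition, combination-therapy
    efficacy and synergy maps, a literature-based parameter derivation
    chain with provenance records, and Latin hypercube / partial rank
    correlation (PRCC) sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    lhs,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
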
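Package: coulisse
Title: Agent-Based Simulation of Multifunctional Bocage Landscapes under
    Agricultural Policy Scenarios
Version: 0.1.0
Authors@R:
    person("Coulisse", "Developers", email = "coulisse@example.org",
           role = c("aut", "cre"))
Description: Spatially explicit agent-based simulator of land-use change in a
    hedgerow-rich (coulissen/bocage) agricultural region. Generates a synthetic
    region of 1-ha parcels, farmer and rural-resident agents and policy zones;
    simulates annual farm succession, cessation, a land market with nature
    organisation and estate buyers, land abandonment and hedgerow/tree-line
    management under two contrasting EU agricultural policy futures (balanced
    targeted support versus abolition of market and income support); and tests
    stakeholder-derived interventions (zoning restrictions on intensive farms,
    cooperation-driven adoption of multifunctional farming, urban in-migration).
    Includes an indicator suite, replicate Monte-Carlo experiment runner,
    sensitivity analysis and map export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
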
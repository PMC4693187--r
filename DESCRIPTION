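Package: pathforge
Title: Integrative Flux, Thermodynamic and Power-Law Analysis of Metabolic Pathways
Version: 0.1.0
Authors@R:
    person("Pathforge", "Developers", email = "pathforge@example.org", role = c("aut", "cre"))
Description: Sequential workflow from constraint-based to dynamic models of small
    metabolic networks: flux balance analysis in primal (maximize objective) and
    swapped (minimize uptake) formulations, thermodynamic feasibility analysis and
    the Max-min Driving Force, thermodynamically aware power-law (S-system) models
    with logarithmic gains, parametric sensitivities and stability margins,
    thermodynamic model shortening by equilibrium metabolite pooling, and
    mathematically controlled comparison of alternative pathway designs. Ships
    fixture generators for an unbranched pathway with end-product inhibition and
    for the bacterial ammonia-assimilation network (GDH versus GS/GOGAT).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
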
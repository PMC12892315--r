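Package: silagetea
Title: Stochastic Techno-Economic Assessment of Grass-Silage Biorefineries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for stochastic techno-economic assessment (TEA) of
    grass-silage biorefineries producing food-grade protein concentrate and,
    optionally, microbial lipids from oleaginous yeast fermentation. Converts
    a design basis and experimental yields into annual product streams,
    estimates total capital investment by factored costing and total
    production cost from operating items, propagates parameter uncertainty
    through Monte Carlo simulation of net present value (NPV), and provides
    one-at-a-time tornado sensitivity, extraction-efficiency, plant-scale and
    discount-rate sweeps, break-even protein pricing, and a radial
    feedstock-catchment model of delivered silage cost on wet and dry-matter
    bases. A seeded fixture generator supplies a fully parameterised example
    cost model, and a command-line entry point ties the stages together.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
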
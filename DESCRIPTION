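Package: mipgreen
Title: Greenness Assessment of Molecularly Imprinted Polymer Synthesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative greenness assessment of molecularly imprinted
    polymer (MIP) synthesis procedures using the twelve-criterion AGREEMIP
    metric. A declarative procedure description (YAML or JSON) listing
    reagents with masses and GHS hazard statements, together with
    categorical synthesis choices, is converted into per-criterion scores
    on a 0-1 scale, a weighted overall score, and a traffic-light
    pictogram. Ships an editable hazard-penalty registry, a weighted
    aggregation engine, a deterministic SVG/PNG pictogram renderer, a
    procedure-file validator, a seeded synthetic-procedure generator, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
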
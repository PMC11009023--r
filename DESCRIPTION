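Package: assayspec
Title: Machine-Readable Specifications of Sequencing-Library Structure
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Defines a machine-readable YAML format that annotates the
    structure of sequencing libraries as an ordered tree of sequence regions
    (adapters, barcodes, unique molecular identifiers, cDNA, linkers), and a
    toolkit to work with such documents: schema and semantic validation,
    extraction of 0-indexed region coordinates, barcode onlist resolution
    (including Cartesian products for split-pool designs), human-readable
    library diagrams, and per-tool technology strings for single-cell RNA-seq
    preprocessors (kallisto|bustools, STARsolo, simpleaf/alevin-fry). Ships a
    deterministic fixture generator and an idealized read simulator so the
    whole toolkit is testable without external data, plus an eleven-subcommand
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tools,
    utils,
    stats,
    yaml
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
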
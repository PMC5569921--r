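Package: flowforge
Title: Assemble and Run Declarative Command-Line Workflows
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Compiles a declarative YAML configuration of reusable
    command-line components into a validated directed-acyclic workflow and
    executes it with run-ID-tagged workspaces, sentinel-based resume,
    breakpoints, forced dependencies, automatic chunk-parallelization over
    genomic intervals with merge, keyword interpolation, and parameter
    sweeping. No hand-written workflow code is required: workflows are
    assembled, validated, frozen into a portable artifact, and run locally
    or through a pluggable batch backend.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    parallel,
    tools,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
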
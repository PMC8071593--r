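Package: cldmapr
Title: Merging Group-Built Causal Loop Diagrams and Classifying Their
    Feedback Loops
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing ensembles of causal loop diagrams (CLDs)
    produced by group model building workshops, such as multi-country
    studies of the drivers of adolescent obesity. Provides a signed-digraph
    CLD data model with theme classification and CSV/GraphML/DOT
    interchange; the hierarchical map-merging protocol (endpoint-variable
    pruning, base-map selection, duplicate/add/park judgment of feeder
    variables, provenance tracking and polarity-conflict resolution) that
    folds group maps into country maps and a single master map; bounded
    enumeration of simple directed cycles with reinforcing/balancing
    classification and theme profiling; a synthetic study generator with
    planted feedback loops for end-to-end validation; and a reproducible
    pipeline that writes audited merge reports, loop reports and renders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
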
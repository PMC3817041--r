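Package: relgraph
Title: Semantic Relationship Graphs from Term Co-Occurrence in Text Corpora
Version: 0.1.0
Authors@R:
    person("Relgraph", "Developers", email = "relgraph@example.org",
           role = c("aut", "cre"))
Description: Infers weighted semantic relationship graphs between two
    controlled vocabularies (for example foods and human diseases) from a
    document corpus by counting per-document term co-occurrences. Supports
    query-centered graph-of-interest extraction, personalization by
    intersection with user-profile graphs, multi-scale graph abstraction,
    deterministic screen-budgeted layout and filtering for small displays,
    GraphML and XML stream serialization, a truncated-SVD latent semantic
    analysis baseline with a dispersion statistic, and a synthetic corpus
    generator with planted co-occurrence structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
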
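# relgraph

Semantic relationship graphs from term co-occurrence in text corpora.

`relgraph` is an R toolkit for inferring and exploring weighted association
networks between two controlled vocabularies — the motivating application is
food–health relationships, with a list of foods as term space *A* and a list
of diseases/conditions as term space *B*. Given a document corpus (a stand-in
for pooled result pages of a meta-search), the package counts, for every
cross-space pair *(a, b)*, the number of documents in which both terms occur:

> w(a, b) = |{ d ∈ D : a ∈ d ∧ b ∈ d }|,  P(a, b) = w(a, b) / |D|

Nodes are terms (coloured by category), edges carry the document-count
weight, the normalized co-occurrence probability, the supporting document
ids, and an optional expert sign label (positive / negative / neutral).
Around this inference core the package provides the machinery of a
graph-based exploratory-search server:

- **Graph of interest (GOI)** — the induced *r*-hop ego subgraph around a
  query term (`extract_goi`), re-centred simply by querying a new term.
- **Personalization** — intersection of a GOI with a user-profile graph
  (`personalize`), with the edge-overlap percentage as its statistic
  (`overlap_fraction`).
- **Multi-scale views** — coarsening the full-detail graph G1 into an
  abstracted G2 (`abstract_graph`; by category, community density, or
  singleton), seeded force-directed layout with a guaranteed minimum node
  separation (`layout_graph`), and filtering to a touch-screen budget of
  `floor(w/t)·floor(h/t)` nodes around the query (`filter_view`).
- **Serialization** — GraphML for interoperability and a schema-validated
  XML stream (`serialize_goi_xml` / `parse_goi_xml`) as the wire format.
- **LSA baseline** — truncated-SVD latent semantic analysis edge weights
  (`lsa_edge_weights`) and a coefficient-of-variation dispersion statistic
  (`weight_dispersion`) quantifying how LSA smooths edge-strength
  differences that plain counting preserves.
- **Synthetic corpora** — `generate_synthetic_corpus` plants exact per-pair
  document counts plus noise, so the whole pipeline can be validated against
  known ground truth without network access.

Who it is for: anyone studying literature-based association mining or
building small-screen graph exploration front-ends who needs a transparent,
deterministic, fully testable reference pipeline.

## Worked example

Load a published strongest-association table, inspect it, and run the
personalization fixture:

```r
library(relgraph)

g <- load_edge_table(system.file("extdata", "table_obesity_edges.tsv",
                                 package = "relgraph"))
compute_metrics(g)
#> graph metrics: 16 nodes, 10 edges, avg node degree 1.250, avg edge weight 961.7
top_associations(g, 3)[c("term_b", "term_a", "weight", "sign")]
#>      term_b term_a weight     sign
#> 1    stroke pepper   2098 positive
#> 2 adiposity   milk   1286  neutral
#> 3     obese  candy    946 negative

ex <- simulate_personalization_example(7)
ex$goi
#> <goi center='palpitations' radius=1: 74 nodes, 73 edges>
p <- personalize(ex$goi, ex$profile)
p
#> <goi center='palpitations' radius=1: 49 nodes, 48 edges>
overlap_fraction(ex$goi, p)
#> [1] 65.8
```

The 10 loaded edges are all the associations stronger than the
reported-by->50-websites publication filter; the strongest (stroke–pepper,
weight 2098, i.e. 2098 supporting documents) ranks first. The seeded
personalization example builds a 74-node/73-edge query-centred star and a
50-node/96-edge user profile sharing the center, 48 leaves and their star
edges; intersecting them keeps 49 nodes and 48 edges — 48/73 = 65.8% of the
GOI's edges survive personalization.

A command-line pipeline over files is available through `run_cli()` (wrapper
script in `inst/cli/relgraph`): subcommands `simulate`, `infer`, `metrics`,
`goi`, `personalize`, `abstract`, `view`, `export`, `lsa`, each writing a
JSON run manifest with parameters, seeds and output hashes.

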
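---
title: "Inferring and exploring term relationship graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring and exploring term relationship graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relgraph)
```

## The model

`relgraph` infers an association network between two disjoint controlled
vocabularies (term spaces *A* and *B*, e.g. foods and diseases/conditions)
from a document corpus. The model is deliberately simple: the strength of
the relationship between a pair *(a, b)* is the number of documents in
which both terms occur,

$$ w(a,b) \;=\; \bigl|\{\, d \in D : a \in d \wedge b \in d \,\}\bigr|,
   \qquad P(a,b) \;=\; \frac{w(a,b)}{|D|}. $$

This is a distributional-co-occurrence method: no parsing, no pattern
extraction, no ontology. Its core assumptions are (i) that a document
mentioning both a food and a condition is weak evidence of an association,
(ii) that evidence accumulates across independent documents, and (iii) that
the corpus is broad enough for frequently co-reported pairs to dominate
spurious ones. Edges carry the supporting document ids, so every inferred
association can be traced back to its evidence; an optional sign label
(positive / negative / neutral) is carried as pass-through metadata —
assigning signs is expert work, not inference.

### Term matching

Documents are case-folded and split on non-alphanumeric characters; a term
(possibly multi-word, e.g. "high cholesterol") matches when its token
sequence occurs contiguously. This is the simplest rule that reproduces
keyword-search semantics and is exactly reproducible. A term matches at
most once per document — **presence, not frequency** — because the weights
are interpreted as "how many pages report this", a document count. A term
may not belong to both spaces: cross-space pairs define the relationship
space, and ambiguous membership would corrupt the bipartite category
colouring, so shared terms are rejected at load time.

Whether multiple pages from the same web site should collapse into one
count is not decidable from the published account ("web pages" vs
"websites"); document-level counting is used, and no domain-level
deduplication is attempted.

### The publication filter

Graphs are built with a *strict* weight threshold: an edge survives when
`weight > min_weight`. The default reporting filter is 50 ("reported by
over 50 websites"); `min_weight = 0` yields the raw graph. Filtering is
monotone: raising the threshold never adds edges. `compute_metrics`
reports the average **node** degree `2E/N`; the phrase "average edge
degree" in the source literature is non-standard, and node degree is the
reading consistent with the handshake lemma.

### Rankings

`top_associations` sorts by weight descending with ties broken
lexicographically by `(term_b, term_a)`. The tie rule carries no meaning;
it exists solely so top-*k* lists are deterministic.

## Exploration and personalization

A **graph of interest** is the induced subgraph on all nodes within
`radius` hops of the query (default `radius = 1`: in a bipartite
association graph a 1-hop ego net is a star, matching the published
74-node/73-edge example). Exploring a new keyword is just a new
`extract_goi` call — there is no separate "re-centre" operation.

**Personalization is graph intersection**: node set
`nodes(GOI) ∩ nodes(profile)`, edge set the edges present in both graphs
under undirected endpoint-pair equality. Weights, probabilities, signs and
document ids are kept from the GOI — profiles encode interest topology,
not strengths. Intersection is commutative in its graph arguments,
idempotent, and yields a subgraph of both inputs. The **overlap statistic
is edge-based**: `100·|E(personalized)|/|E(GOI)|`, rounded to one decimal.
The choice is forced by the published worked example: 48/73 = 65.8%
matches the printed figure, while the node ratio 49/74 = 66.2% does not.

The profiles evaluated in the source study were never published, so
`simulate_personalization_example` constructs the worked example
deterministically from a seed: a 73-leaf star GOI and a 50-node/96-edge
profile sharing the center, 48 leaves and the 48 corresponding star edges,
its other 48 edges drawn among profile nodes in configurations absent from
the star. Every intersection count (49 nodes, 48 edges, 65.8%) then follows
by construction for *any* seed — the seed varies which leaves are shared
and the edge weights, not the arithmetic.

## Multi-scale views for small screens

The server-side result-processing pipeline is: group → layout → filter →
serialize.

**Grouping** (`abstract_graph`) coarsens the full-detail graph G1 into G2.
The published grouping rule ("graph level and node/edge density") is
underspecified, so the default policy is the one unambiguous structure the
data carries: one group per term-space category (a bipartite graph
collapses to two supernodes). A `density` policy (greedy modularity
communities on the weighted graph, deterministic) and a `singleton`
identity policy sit behind the same interface. Superedge weight is the sum
of member cross-group edge weights, so total cross-group weight is
conserved under every policy; each group is labelled by its highest-degree
member (ties lexicographic).

**Layout** (`layout_graph`) must produce an "easily clickable" graph, which
we operationalize as a minimum pairwise node distance in scaled pixels
(default: the touch target). A Fruchterman–Reingold layout runs under a
fixed seed (mandatory argument, documented default 7), followed by a
deterministic push-apart relaxation; if violations persist, nodes are
snapped to free cells of the touch-target grid. The fallback makes the
separation a hard guarantee whenever the node count fits the grid — a
best-effort layout that usually separates nodes is not testable, a
guaranteed one is. Positions are stored normalized to the unit square
(origin top-left, x right, y down, the device convention) and scaled at
render time.

**Filtering** (`filter_view`) keeps the query node plus, breadth-first from
the retained set, the neighbours with the heaviest edge into the retained
set, until the budget `⌊w/t⌋·⌊h/t⌋` is reached (220 for a 1080×1920 screen
with 96 px targets — 96 px is a comfortable fingertip target at ~480 dpi).
Growing along maximum-weight frontier edges keeps the result connected
whenever the input is. A budget at least the graph order returns the graph
unchanged (relevant for disconnected graphs, which breadth-first growth
alone could never cover).

**Serialization**: the wire format is a small XML stream —
`<goi level centre>` with `<node id label category colour x y/>` and
`<edge source target weight sign colour><url>…</url></edge>` — fixed here
by declared convention (the original element vocabulary was never
published) and validated against the XSD shipped in `inst/extdata/goi.xsd`.
Edge colour is the channel-wise floored mean of the endpoint colours.
Positions are written with 17 significant digits so the round trip is exact
at double precision. GraphML import/export (via igraph) is provided for
interoperability; a graph-level attribute records which side of each edge
belongs to space A, since GraphML itself has no edge orientation.

## The LSA baseline

The comparison baseline is standard latent semantic analysis: truncated
SVD of the raw term–document count matrix (vocabulary = both term spaces),
term vectors `U_k Σ_k`, edge weight the cosine similarity of the two latent
vectors clipped below at zero (edge strengths are non-negative). No tf-idf
or log-entropy weighting is applied: the baseline is meant to be minimal
and deterministic, not a clone of any particular LSA package — the original
comparison used a third-party LSA tool whose internal weighting is
undocumented, so only the qualitative claim is reproduced. Default latent
dimension: `min(100, rank − 1)`.

The claim itself — that LSA *smooths out the intrinsic differences between
edge strengths* — is formalized with the population coefficient of
variation `sd(w)/mean(w)` (`weight_dispersion`), a scale-free dispersion
measure. On planted corpora whose pair counts span more than an order of
magnitude, co-occurrence weights must out-disperse LSA weights over the
same pairs in ≥ 90% of seeded replicates; that property, not any particular
edge value, is the reproducible content of the comparison.

## The synthetic world

`generate_synthetic_corpus` emulates pooled meta-search result pages with
known ground truth. Each planted pair contributes exactly `count` documents
containing both phrases separated by filler tokens drawn from a vocabulary
provably disjoint from every term token, so no filler run can complete a
phrase match; noise documents contain terms from at most one space. The
generator re-matches every document it builds and fails if the requested
term spaces make exact planting impossible (e.g. one term nested inside
another, which would create unplanted cross-space pairs). Everything is
deterministic given the seed.

Default world for the planted-recovery criterion: 20 pairs over a 5×4 term
grid with counts spanning 1–200 plus 40 noise documents (≤ 500 documents
total); for the smoothing criterion, counts are log-uniform on [2, 200]
with 30 noise documents, 20 replicates. These sizes mirror the scale of the
published test-beds (11 × 27 terms, top weights ~600–2100) shrunk to
desk-scale corpora.

What the generator does **not** emulate — and therefore what a green test
does not establish: real pages are not disjoint bags of filler (terms
co-occur incidentally, negations and list pages confound counts), real
corpora are not balanced across pairs, and search-engine result pooling
introduces duplication and ranking bias. Green planted-recovery tests
establish that the counting machinery is exact, not that document counts
are good estimates of semantic relatedness on the live web. Likewise the
published corpus-scale metrics (average degree 80, average weight 978) and
the user-survey scores depend on the 2013 web corpus and human subjects and
are out of reach by design.

## Numerical and degenerate-input choices

- Empty corpus → empty association list (not an error); empty graph →
  `compute_metrics` errors ("empty graph").
- Unknown GOI query → error listing the three lexically nearest node terms.
- An edgeless GOI has no defined overlap fraction (error), an empty
  personalized GOI has overlap 0.
- LSA terms absent from the corpus get weight 0 with a warning; an
  all-zero weight vector has no defined dispersion (error).
- `mix_color` floors the channel mean, keeping channels in `[0, 255]`.
- All randomness (synthetic corpora, layouts, fixtures) flows through
  explicit integer seeds; repeated runs are byte-identical.

## Known limitations

Counting is O(|D|·(|A|+|B|)) with plain R loops — fine for desk-scale
corpora (hundreds to thousands of documents), not engineered for
dozens-of-thousands-term spaces. No stemming or lemmatization: "oat" and
"oats" are different terms, as they are in the published tables. Sign
labels are metadata, never inferred; causal claims are explicitly out of
scope. Profile learning from click history is not implemented — profiles
are inputs.
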
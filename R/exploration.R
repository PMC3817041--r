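#' Graph of interest (GOI)
#'
#' The query-centered subgraph handed to a user for visual exploration: the
#' induced subgraph on all nodes within `radius` hops of the query term.
#'
#' @param graph a `relationship_graph`.
#' @param query the query term (normalized before lookup).
#' @param radius hop count; `0` yields the single query node with no edges.
#'   Default `1`, the ego neighbourhood.
#' @return An object of class `goi` with fields `center`, `graph`
#'   (`relationship_graph`), `radius` and `center_dropped`.
#' @export
extract_goi <- function(graph, query, radius = 1L) {
  stopifnot(inherits(graph, "relationship_graph"), radius >= 0)
  query <- normalize_term(query)
  if (!(query %in% graph$nodes$term)) {
    near <- nearest_terms(query, graph$nodes$term)
    stop("query term '", query, "' not in graph; nearest matches: ",
         paste(near, collapse = ", "))
  }
  frontier <- query
  reached <- query
  hops <- 0L
  while (hops < radius && length(frontier) > 0L) {
    e <- graph$edges
    nb <- c(e$term_b[e$term_a %in% frontier], e$term_a[e$term_b %in% frontier])
    frontier <- setdiff(nb, reached)
    reached <- c(reached, frontier)
    hops <- hops + 1L
  }
  sub <- induced_subgraph_rg(graph, reached)
  if (radius == 0L) sub$edges <- canonical_edges(empty_edges())
  structure(list(center = query, graph = sub, radius = as.integer(radius),
                 center_dropped = FALSE),
            class = "goi")
}

nearest_terms <- function(query, terms, n = 3L) {
  d <- utils::adist(query, terms)[1, ]
  terms[order(d, terms)][seq_len(min(n, length(terms)))]
}

#' @export
print.goi <- function(x, ...) {
  cat(sprintf("<goi center='%s' radius=%d: %d nodes, %d edges%s>\n",
              x$center, x$radius, node_count(x$graph), edge_count(x$graph),
              if (x$center_dropped) " [center dropped]" else ""))
  invisible(x)
}

#' User-profile graphs
#'
#' A user profile is a plain graph over the term vocabulary encoding one
#' user's interests; personalization intersects it with a GOI. Profile
#' edges carry no weights — interest is topology, strengths come from the
#' inferred relationship graph.
#'
#' @param id profile label.
#' @param nodes character vector of node terms.
#' @param edges data frame with columns `from`, `to` (undirected, no
#'   self-loops or duplicate pairs).
#' @return An object of class `user_profile`.
#' @export
user_profile <- function(id, nodes, edges) {
  nodes <- unique(normalize_term(nodes))
  edges <- data.frame(from = normalize_term(edges$from),
                      to = normalize_term(edges$to),
                      stringsAsFactors = FALSE)
  if (any(edges$from == edges$to)) stop("profile has self-loops")
  key <- pair_key(edges$from, edges$to)
  if (anyDuplicated(key)) stop("profile has duplicate edges")
  missing <- setdiff(c(edges$from, edges$to), nodes)
  if (length(missing)) nodes <- c(nodes, missing)
  structure(list(id = id, nodes = nodes, edges = edges),
            class = "user_profile")
}

#' @export
print.user_profile <- function(x, ...) {
  cat(sprintf("<user_profile '%s': %d nodes, %d edges>\n", x$id,
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# canonical undirected pair key
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Read / write user profiles as GraphML
#'
#' @param path GraphML file path.
#' @param id profile label; defaults to the file stem.
#' @return A [user_profile()].
#' @export
read_profile <- function(path, id = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("profile file not found: ", path)
  ig <- igraph::read_graph(path, format = "graphml")
  user_profile(id, igraph::V(ig)$name,
               igraph::as_data_frame(ig, what = "edges")[c("from", "to")])
}

#' @param profile a [user_profile()].
#' @rdname read_profile
#' @export
write_profile <- function(profile, path) {
  ig <- igraph::graph_from_data_frame(profile$edges, directed = FALSE,
                                      vertices = data.frame(
                                        name = profile$nodes))
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

# node set + undirected edge-key set, for any supported graph-like object
graph_sets <- function(x) {
  if (inherits(x, "goi")) x <- x$graph
  if (inherits(x, "relationship_graph")) {
    list(nodes = x$nodes$term, keys = pair_key(x$edges$term_a, x$edges$term_b))
  } else if (inherits(x, "user_profile")) {
    list(nodes = x$nodes, keys = pair_key(x$edges$from, x$edges$to))
  } else {
    stop("unsupported graph object of class ", paste(class(x), collapse = "/"))
  }
}

#' Personalize a GOI by graph intersection
#'
#' The personalized GOI is the intersection graph: its node set is
#' `nodes(goi) ∩ nodes(profile)` and its edge set contains the edges present
#' in both graphs (undirected endpoint-pair equality). Edge weights,
#' probabilities, signs and document ids are kept from the GOI. An empty
#' intersection is legal; if the query node itself is dropped the result is
#' flagged `center_dropped`.
#'
#' @param goi a [extract_goi()] result.
#' @param profile a [user_profile()] (or any graph-like object).
#' @return A `goi`.
#' @export
personalize <- function(goi, profile) {
  stopifnot(inherits(goi, "goi"))
  p <- graph_sets(profile)
  keep_nodes <- intersect(goi$graph$nodes$term, p$nodes)
  g <- goi$graph
  nodes <- g$nodes[g$nodes$term %in% keep_nodes, , drop = FALSE]
  in_both <- pair_key(g$edges$term_a, g$edges$term_b) %in% p$keys &
    g$edges$term_a %in% keep_nodes & g$edges$term_b %in% keep_nodes
  sub <- new_relationship_graph(nodes, g$edges[in_both, , drop = FALSE],
                                g$provenance)
  structure(list(center = goi$center, graph = sub, radius = goi$radius,
                 center_dropped = !(goi$center %in% keep_nodes)),
            class = "goi")
}

#' Edge overlap between a GOI and its personalized version
#'
#' `100 * |edges(personalized)| / |edges(goi)|`, rounded to one decimal —
#' the personalization statistic reported for profile intersections.
#'
#' @param goi the original `goi` (must have at least one edge).
#' @param personalized the personalized `goi`.
#' @return Percentage in `[0, 100]`, rounded to one decimal place.
#' @export
overlap_fraction <- function(goi, personalized) {
  stopifnot(inherits(goi, "goi"), inherits(personalized, "goi"))
  n <- edge_count(goi$graph)
  if (n == 0L) stop("edgeless GOI")
  round(100 * edge_count(personalized$graph) / n, 1)
}

#' Seeded worked example: star GOI and a partially overlapping profile
#'
#' Builds the deterministic fixture used throughout the tests: a 1-hop GOI
#' around the condition term "palpitations" with 73 food neighbours (74
#' nodes, 73 edges), and a user profile of 50 nodes and 96 edges that shares
#' the center, 48 of the leaves and the 48 corresponding star edges; the
#' profile's remaining 48 edges connect profile nodes in ways absent from
#' the star. Intersection therefore yields 49 nodes and 48 edges, an edge
#' overlap of 65.8%.
#'
#' @param seed integer seed for leaf selection, extra profile edges and
#'   weights.
#' @return List with elements `graph` (the star as a
#'   `relationship_graph`), `goi`, and `profile`.
#' @export
simulate_personalization_example <- function(seed = 7L) {
  with_local_seed(seed, {
    center <- "palpitations"
    leaves <- sprintf("food%02d", 1:73)
    space_a <- term_space(leaves, "foods", "food", c(0L, 153L, 0L))
    space_b <- term_space(center, "conditions", "condition", c(204L, 0L, 0L))
    assoc <- data.frame(term_a = leaves, term_b = center,
                        weight = sample(60:2000, 73), stringsAsFactors = FALSE)
    graph <- build_relationship_graph(assoc, min_weight = 0,
                                      space_a = space_a, space_b = space_b,
                                      provenance = "synthetic star fixture")
    goi <- extract_goi(graph, center, radius = 1L)

    shared <- sort(sample(leaves, 48))
    extra_node <- "exercise"
    prof_nodes <- c(center, shared, extra_node)
    star_edges <- data.frame(from = center, to = shared,
                             stringsAsFactors = FALSE)
    # 48 extra edges among profile nodes that do not exist in the star:
    # leaf-leaf pairs and leaf-extra_node pairs
    cand_from <- c(utils::combn(shared, 2)[1, ], shared)
    cand_to <- c(utils::combn(shared, 2)[2, ], rep(extra_node, length(shared)))
    pick <- sample(length(cand_from), 48)
    profile <- user_profile("synthetic-user",
                            prof_nodes,
                            rbind(star_edges,
                                  data.frame(from = cand_from[pick],
                                             to = cand_to[pick],
                                             stringsAsFactors = FALSE)))
    list(graph = graph, goi = goi, profile = profile)
  })
}
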
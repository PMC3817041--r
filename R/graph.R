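#' Relationship graphs
#'
#' A relationship graph is a weighted, bipartite-flavoured simple graph:
#' nodes are terms carrying a category and colour, edges are cross-space
#' associations carrying a document-count weight, a normalized probability,
#' the supporting document ids, and an optional sign label
#' (positive / negative / neutral).
#'
#' @name relationship_graph
#' @keywords internal
NULL

new_relationship_graph <- function(nodes, edges, provenance = NA_character_) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  g <- structure(list(nodes = nodes, edges = edges, provenance = provenance),
                 class = "relationship_graph")
  validate_relationship_graph(g)
}

validate_relationship_graph <- function(g) {
  nodes <- g$nodes
  edges <- g$edges
  stopifnot(all(c("term", "category", "color") %in% names(nodes)),
            all(c("term_a", "term_b", "weight") %in% names(edges)))
  if (anyDuplicated(nodes$term)) stop("duplicate nodes")
  if (nrow(edges) > 0) {
    if (any(edges$term_a == edges$term_b)) stop("self-loops are not allowed")
    key <- paste(edges$term_a, edges$term_b, sep = "\r")
    if (anyDuplicated(key)) stop("duplicate edges")
    missing <- setdiff(c(edges$term_a, edges$term_b), nodes$term)
    if (length(missing)) {
      stop("edge endpoints missing from node set: ",
           paste(missing, collapse = ", "))
    }
    cat_of <- stats::setNames(nodes$category, nodes$term)
    same <- cat_of[edges$term_a] == cat_of[edges$term_b]
    if (any(same)) {
      stop("edges must connect terms from different spaces; offending: ",
           paste(edges$term_a[same], edges$term_b[same], sep = "--",
                 collapse = ", "))
    }
    if (any(edges$weight < 0)) stop("edge weights must be non-negative")
  }
  g
}

#' @export
print.relationship_graph <- function(x, ...) {
  cat(sprintf("<relationship_graph: %d nodes, %d edges>\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges
#'
#' @param g a `relationship_graph`.
#' @return Integer count.
#' @export
node_count <- function(g) nrow(g$nodes)

#' @rdname node_count
#' @export
edge_count <- function(g) nrow(g$edges)

empty_edges <- function() {
  data.frame(term_a = character(0), term_b = character(0),
             weight = numeric(0), probability = numeric(0),
             sign = character(0), stringsAsFactors = FALSE)
}

# Ensure optional association columns exist, weights are numeric (GraphML
# stores doubles) and doc_ids is a list-column.
canonical_edges <- function(edges) {
  edges$weight <- as.numeric(edges$weight)
  if (is.null(edges$probability)) edges$probability <- rep(NA_real_, nrow(edges))
  if (is.null(edges$sign)) edges$sign <- rep(NA_character_, nrow(edges))
  if (is.null(edges$doc_ids)) {
    edges$doc_ids <- replicate(nrow(edges), character(0), simplify = FALSE)
  }
  edges[c("term_a", "term_b", "weight", "probability", "sign", "doc_ids")]
}

# Induced subgraph on a set of node terms (edges with both endpoints kept).
induced_subgraph_rg <- function(g, terms) {
  nodes <- g$nodes[g$nodes$term %in% terms, , drop = FALSE]
  keep <- g$edges$term_a %in% terms & g$edges$term_b %in% terms
  new_relationship_graph(nodes, g$edges[keep, , drop = FALSE], g$provenance)
}

col_hex <- function(rgb) sprintf("#%02X%02X%02X", rgb[1], rgb[2], rgb[3])

hex_col <- function(hex) {
  as.integer(c(strtoi(substr(hex, 2, 3), 16L), strtoi(substr(hex, 4, 5), 16L),
               strtoi(substr(hex, 6, 7), 16L)))
}

#' Convert a relationship graph to an igraph object
#'
#' Vertex attributes `category` and `color`; edge attributes `weight`,
#' `probability`, `sign` and `doc_ids` (comma-joined).
#'
#' @param g a `relationship_graph`.
#' @return An [igraph::graph] (undirected).
#' @export
as_igraph <- function(g) {
  edges <- g$edges
  e_df <- data.frame(from = edges$term_a, to = edges$term_b,
                     weight = edges$weight,
                     probability = if (is.null(edges$probability))
                       NA_real_ else edges$probability,
                     sign = sign_to_chr(edges$sign),
                     doc_ids = vapply(edges$doc_ids %||%
                                        replicate(nrow(edges), character(0),
                                                  simplify = FALSE),
                                      paste, character(1), collapse = ","),
                     stringsAsFactors = FALSE)
  ig <- igraph::graph_from_data_frame(e_df, directed = FALSE,
                                      vertices = g$nodes[c("term", "category",
                                                           "color")])
  if (nrow(edges) > 0) {
    # remember which side of each edge belongs to space A so the GraphML
    # round trip restores the original orientation
    cat_of <- stats::setNames(g$nodes$category, g$nodes$term)
    ig <- igraph::set_graph_attr(ig, "category_a",
                                 unname(cat_of[edges$term_a[1]]))
  }
  ig
}

sign_to_chr <- function(sign) {
  if (is.null(sign)) return(character(0))
  ifelse(is.na(sign), "", sign)
}

chr_to_sign <- function(x) {
  out <- as.character(x)
  out[!nzchar(out) | is.na(out)] <- NA_character_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a relationship graph as GraphML
#'
#' GraphML is used for interoperability (profiles, external viewers); the
#' round trip is exact on nodes, edges, weights, probabilities, signs and
#' supporting document ids.
#'
#' @param g a `relationship_graph`.
#' @param path file path.
#' @return `write_graphml` returns `path` invisibly; `read_graphml` returns
#'   a `relationship_graph`.
#' @export
write_graphml <- function(g, path) {
  ig <- as_igraph(g)
  # igraph writes NA numerics as NaN; normalize on read instead
  igraph::write_graph(ig, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("GraphML file not found: ", path)
  ig <- igraph::read_graph(path, format = "graphml")
  igraph_to_rg(ig, provenance = path)
}

igraph_to_rg <- function(ig, provenance = NA_character_) {
  v <- igraph::as_data_frame(ig, what = "vertices")
  e <- igraph::as_data_frame(ig, what = "edges")
  nodes <- data.frame(term = v$name,
                      category = v$category %||% rep("term", nrow(v)),
                      color = v$color %||% rep("#7F7F7F", nrow(v)),
                      stringsAsFactors = FALSE)
  if (nrow(e) == 0) {
    edges <- canonical_edges(empty_edges())
  } else {
    prob <- e$probability %||% rep(NA_real_, nrow(e))
    prob[is.nan(prob)] <- NA_real_
    edges <- data.frame(term_a = e$from, term_b = e$to,
                        weight = e$weight %||% rep(1, nrow(e)),
                        probability = prob,
                        sign = chr_to_sign(e$sign %||% rep("", nrow(e))),
                        stringsAsFactors = FALSE)
    ids <- e$doc_ids %||% rep("", nrow(e))
    edges$doc_ids <- lapply(strsplit(ifelse(is.na(ids), "", ids), ",",
                                     fixed = TRUE),
                            function(x) x[nzchar(x)])
  }
  # orient each edge so term_a lies in space A (per the category_a graph
  # attribute when present, else the lexicographically smaller category)
  cat_of <- stats::setNames(nodes$category, nodes$term)
  if (nrow(edges) > 0) {
    cat_a <- if ("category_a" %in% igraph::graph_attr_names(ig)) {
      igraph::graph_attr(ig, "category_a")
    } else {
      min(cat_of[edges$term_a], cat_of[edges$term_b])
    }
    flip <- cat_of[edges$term_a] != cat_a
    tmp <- edges$term_a[flip]
    edges$term_a[flip] <- edges$term_b[flip]
    edges$term_b[flip] <- tmp
  }
  new_relationship_graph(nodes, edges, provenance)
}
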
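#' Count cross-space co-occurrences in a corpus
#'
#' The primitive of relationship-graph inference: for every pair `(a, b)`
#' with `a` in space A and `b` in space B that appear together in at least
#' one document, count the number of documents containing both. Document
#' presence (not token frequency) is what is counted, so a pair's weight is
#' "how many pages report this association". The normalized `probability`
#' column is `weight / corpus size`.
#'
#' @param corp a [corpus()].
#' @param space_a,space_b two [term_space()] objects with disjoint terms.
#' @return A data frame of associations with columns `term_a`, `term_b`,
#'   `weight`, `probability`, `sign` (`NA`), and list-column `doc_ids`
#'   (supporting document ids, sorted). Rows are sorted by
#'   `(term_a, term_b)`. The input spaces are attached as attributes
#'   `space_a` / `space_b`.
#' @export
count_cooccurrences <- function(corp, space_a, space_b) {
  stopifnot(inherits(corp, "corpus"),
            inherits(space_a, "term_space"), inherits(space_b, "term_space"))
  overlap <- intersect(space_a$terms, space_b$terms)
  if (length(overlap)) {
    stop("term spaces must be disjoint; shared terms: ",
         paste(overlap, collapse = ", "))
  }
  acc <- new.env(parent = emptyenv())
  for (d in corp$documents) {
    ma <- match_terms(d, space_a)
    if (length(ma) == 0L) next
    mb <- match_terms(d, space_b)
    for (a in ma) for (b in mb) {
      key <- paste(a, b, sep = "\r")
      acc[[key]] <- c(acc[[key]], d$id)
    }
  }
  keys <- sort(ls(acc))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  doc_ids <- lapply(keys, function(k) sort(acc[[k]]))
  assoc <- data.frame(
    term_a = vapply(parts, `[`, character(1), 1L),
    term_b = vapply(parts, `[`, character(1), 2L),
    weight = vapply(doc_ids, length, integer(1)),
    stringsAsFactors = FALSE)
  assoc$probability <- if (corp$size > 0) assoc$weight / corp$size else numeric(0)
  assoc$sign <- rep(NA_character_, nrow(assoc))
  assoc$doc_ids <- doc_ids
  attr(assoc, "space_a") <- space_a
  attr(assoc, "space_b") <- space_b
  assoc
}

#' Build a filtered relationship graph from associations
#'
#' Keeps exactly the associations with weight strictly greater than
#' `min_weight` (the publication filter is "reported by over 50 websites",
#' i.e. `min_weight = 50`), plus their endpoint nodes; isolated nodes are
#' dropped.
#'
#' @param associations association data frame as returned by
#'   [count_cooccurrences()] or assembled by hand.
#' @param min_weight non-negative strict threshold; `0` keeps every
#'   positive-weight association.
#' @param space_a,space_b the [term_space()] objects providing node
#'   categories and colours; default to the attributes attached by
#'   [count_cooccurrences()].
#' @param provenance free-text origin recorded on the graph.
#' @return A `relationship_graph`.
#' @export
build_relationship_graph <- function(associations, min_weight = 0,
                                     space_a = attr(associations, "space_a"),
                                     space_b = attr(associations, "space_b"),
                                     provenance = NA_character_) {
  if (min_weight < 0) stop("min_weight must be non-negative")
  stopifnot(inherits(space_a, "term_space"), inherits(space_b, "term_space"))
  edges <- canonical_edges(
    associations[associations$weight > min_weight, , drop = FALSE])
  nodes <- graph_nodes(edges, space_a, space_b)
  new_relationship_graph(nodes, edges, provenance)
}

graph_nodes <- function(edges, space_a, space_b) {
  ta <- sort(unique(edges$term_a))
  tb <- sort(unique(edges$term_b))
  bad <- c(setdiff(ta, space_a$terms), setdiff(tb, space_b$terms))
  if (length(bad)) {
    stop("association terms not found in their term space: ",
         paste(bad, collapse = ", "))
  }
  data.frame(
    term = c(ta, tb),
    category = c(rep(space_a$category, length(ta)),
                 rep(space_b$category, length(tb))),
    color = c(rep(col_hex(space_a$color), length(ta)),
              rep(col_hex(space_b$color), length(tb))),
    stringsAsFactors = FALSE)
}

#' Graph-theoretic summary metrics
#'
#' Average node degree (`2 * edges / nodes` for a simple graph), average
#' edge weight, and node/edge counts.
#'
#' @param g a non-empty `relationship_graph`.
#' @return A list of class `graph_metrics` with fields `node_count`,
#'   `edge_count`, `avg_node_degree`, `avg_edge_weight`.
#' @export
compute_metrics <- function(g) {
  stopifnot(inherits(g, "relationship_graph"))
  if (node_count(g) == 0L) stop("empty graph")
  structure(list(
    node_count = node_count(g),
    edge_count = edge_count(g),
    avg_node_degree = 2 * edge_count(g) / node_count(g),
    avg_edge_weight = if (edge_count(g) > 0) mean(g$edges$weight) else NaN
  ), class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf(paste0("graph metrics: %d nodes, %d edges, ",
                     "avg node degree %.3f, avg edge weight %.1f\n"),
              x$node_count, x$edge_count, x$avg_node_degree,
              x$avg_edge_weight))
  invisible(x)
}

#' Strongest associations in a graph
#'
#' The `k` highest-weight edges, weight descending; ties are broken
#' lexicographically by `(term_b, term_a)` so the ranking is deterministic.
#' Fewer rows are returned when the graph has fewer edges.
#'
#' @param g a `relationship_graph`.
#' @param k positive number of associations to return.
#' @return Association data frame (same columns as the graph's edges).
#' @export
top_associations <- function(g, k) {
  stopifnot(inherits(g, "relationship_graph"), k >= 1)
  e <- g$edges
  ord <- order(-e$weight, e$term_b, e$term_a)
  out <- e[utils::head(ord, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load a printed edge table as a relationship graph
#'
#' Reads a headerless TSV whose rows are `term_b <TAB> term_a <TAB> weight`
#' with an optional fourth sign column (parenthesized labels such as
#' `(positive)` are accepted). This matches the layout of published
#' strongest-association tables, which list the condition term first.
#'
#' @param path TSV file path.
#' @param space_a,space_b optional [term_space()] objects used to validate
#'   terms and supply node colours. When `NULL`, minimal term spaces are
#'   derived from the table itself (printed tables may use word forms absent
#'   from the full vocabulary).
#' @param strict if `TRUE`, a row whose term is missing from the supplied
#'   spaces is an error; otherwise it is skipped with a warning.
#' @param category_a,category_b,color_a,color_b category labels and RGB
#'   colours used when deriving term spaces from the table.
#' @return A `relationship_graph` with empty `doc_ids` and `NA`
#'   probabilities (the source corpus is unknown).
#' @export
load_edge_table <- function(path, space_a = NULL, space_b = NULL,
                            strict = FALSE,
                            category_a = "food", category_b = "condition",
                            color_a = c(0L, 153L, 0L),
                            color_b = c(204L, 0L, 0L)) {
  if (!file.exists(path)) stop("edge table not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    sa <- space_a %||% term_space("(none)", "A", category_a, color_a)
    sb <- space_b %||% term_space("(none)", "B", category_b, color_b)
    return(new_relationship_graph(graph_nodes(empty_edges(), sa, sb),
                                  canonical_edges(empty_edges()), path))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) stop("malformed edge-table row ", bad[1], ": ", lines[bad[1]])
  term_b <- normalize_term(vapply(fields, `[`, character(1), 1L))
  term_a <- normalize_term(vapply(fields, `[`, character(1), 2L))
  weight <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  if (anyNA(weight)) {
    stop("malformed edge-table weight in row ", which(is.na(weight))[1])
  }
  sign <- vapply(fields, function(f) {
    if (length(f) >= 4L) gsub("[()]", "", trimws(f[4])) else ""
  }, character(1))
  sign <- chr_to_sign(tolower(sign))
  known <- sign %in% c("positive", "negative", "neutral") | is.na(sign)
  if (any(!known)) stop("unknown sign label: ", sign[!known][1])

  if (is.null(space_a)) {
    space_a <- term_space(unique(term_a), "tableA", category_a, color_a)
  }
  if (is.null(space_b)) {
    space_b <- term_space(unique(term_b), "tableB", category_b, color_b)
  }
  unknown <- !(term_a %in% space_a$terms) | !(term_b %in% space_b$terms)
  if (any(unknown)) {
    msg <- paste0("edge table rows with unknown terms: ",
                  paste(paste(term_b[unknown], term_a[unknown], sep = "--"),
                        collapse = ", "))
    if (strict) stop(msg) else warning(msg, "; skipped")
  }
  edges <- canonical_edges(data.frame(
    term_a = term_a[!unknown], term_b = term_b[!unknown],
    weight = weight[!unknown], sign = sign[!unknown],
    stringsAsFactors = FALSE))
  new_relationship_graph(graph_nodes(edges, space_a, space_b), edges, path)
}

#' Write associations as an edge-table TSV
#'
#' Mirrors [load_edge_table()]'s layout (`term_b`, `term_a`, `weight`,
#' `sign`) so inferred and LSA edge weights can be compared side by side.
#'
#' @param edges association data frame or `relationship_graph`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(edges, path) {
  if (inherits(edges, "relationship_graph")) edges <- edges$edges
  sign <- sign_to_chr(edges$sign %||% rep(NA_character_, nrow(edges)))
  lines <- sprintf("%s\t%s\t%s\t%s", edges$term_b, edges$term_a,
                   format(edges$weight, trim = TRUE, digits = 15,
                          scientific = FALSE),
                   sign)
  writeLines(sub("\t$", "", lines), path, useBytes = TRUE)
  invisible(path)
}
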
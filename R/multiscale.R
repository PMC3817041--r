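#' Screen view specification
#'
#' Describes the display a graph view must fit: pixel dimensions and the
#' minimum clickable (touch-target) size. The node budget of a view is
#' `floor(width / touch_target) * floor(height / touch_target)` — the number
#' of touch-sized cells that tile the screen.
#'
#' @param width,height screen size in pixels.
#' @param touch_target minimum clickable size in pixels (default 96, a
#'   comfortable fingertip target on a high-DPI phone).
#' @param center the query term at the center of the view.
#' @return An object of class `view_spec`.
#' @examples
#' view_budget(view_spec(1080, 1920, 96))  # 11 * 20 = 220 nodes
#' @export
view_spec <- function(width, height, touch_target = 96, center = NULL) {
  stopifnot(width > 0, height > 0, touch_target > 0)
  structure(list(width = width, height = height,
                 touch_target = touch_target,
                 center = if (is.null(center)) NULL else normalize_term(center)),
            class = "view_spec")
}

#' @param view a [view_spec()].
#' @rdname view_spec
#' @export
view_budget <- function(view) {
  floor(view$width / view$touch_target) * floor(view$height / view$touch_target)
}

# Uniform node/edge frame for layout and serialization: nodes
# (term, label, category, color), edges (term_a, term_b, weight, sign,
# doc_ids), plus a level index (0 = full detail).
graph_frame <- function(x) {
  if (inherits(x, "goi")) x <- x$graph
  if (inherits(x, "relationship_graph")) {
    nodes <- x$nodes
    nodes$label <- nodes$term
    return(list(nodes = nodes[c("term", "label", "category", "color")],
                edges = canonical_edges(x$edges), level = 0L))
  }
  if (inherits(x, "abstract_graph")) {
    nodes <- x$supernodes
    return(list(nodes = data.frame(term = nodes$id, label = nodes$label,
                                   category = nodes$category,
                                   color = nodes$color,
                                   stringsAsFactors = FALSE),
                edges = canonical_edges(x$superedges), level = x$level))
  }
  stop("unsupported graph object of class ", paste(class(x), collapse = "/"))
}

#' Coarsen a relationship graph into an abstracted graph
#'
#' Groups the full-detail graph (G1) into supernodes and aggregated
#' superedges (G2) for multi-scale display. Policies:
#' \describe{
#'   \item{`category`}{one group per term-space category (default; a
#'     bipartite graph collapses to two supernodes).}
#'   \item{`density`}{greedy modularity-based community grouping on the
#'     weighted graph (deterministic).}
#'   \item{`singleton`}{every node its own group — an identity abstraction.}
#' }
#' A superedge's weight is the sum of the member edge weights crossing the
#' two groups; each group's representative label is its highest-degree
#' member (ties broken lexicographically).
#'
#' @param g a non-empty `relationship_graph` (or `goi`).
#' @param policy grouping policy.
#' @return An object of class `abstract_graph` with fields `supernodes`
#'   (id, label, category, color, size + `members` list), `superedges`,
#'   `level` (1) and `policy`.
#' @export
abstract_graph <- function(g, policy = c("category", "density", "singleton")) {
  if (inherits(g, "goi")) g <- g$graph
  stopifnot(inherits(g, "relationship_graph"))
  if (node_count(g) == 0L) stop("empty graph")
  policy <- match.arg(policy)
  terms <- g$nodes$term
  membership <- switch(policy,
    category = match(g$nodes$category, sort(unique(g$nodes$category))),
    singleton = seq_along(terms),
    density = {
      ig <- as_igraph(g)
      comm <- igraph::cluster_fast_greedy(ig,
        weights = if (edge_count(g) > 0) igraph::E(ig)$weight else NULL)
      igraph::membership(comm)[terms]
    })
  groups <- split(terms, membership)
  names(groups) <- NULL

  deg <- table(factor(c(g$edges$term_a, g$edges$term_b), levels = terms))
  supernodes <- do.call(rbind, lapply(seq_along(groups), function(i) {
    members <- sort(groups[[i]])
    d <- deg[members]
    label <- members[order(-as.integer(d), members)][1]
    cats <- unique(g$nodes$category[g$nodes$term %in% members])
    cols <- vapply(g$nodes$color[g$nodes$term %in% members], hex_col,
                   integer(3))
    data.frame(id = sprintf("g%02d", i), label = label,
               category = if (length(cats) == 1L) cats else "mixed",
               color = col_hex(as.integer(floor(rowMeans(cols)))),
               size = length(members), stringsAsFactors = FALSE)
  }))
  supernodes$members <- lapply(groups, sort)

  grp_of <- stats::setNames(rep(supernodes$id, lengths(groups)),
                            unlist(groups))
  e <- g$edges
  ga <- grp_of[e$term_a]
  gb <- grp_of[e$term_b]
  cross <- ga != gb
  if (any(cross)) {
    key_lo <- pmin(ga[cross], gb[cross])
    key_hi <- pmax(ga[cross], gb[cross])
    agg <- stats::aggregate(list(weight = e$weight[cross]),
                            by = list(term_a = key_lo, term_b = key_hi), sum)
    superedges <- agg[order(agg$term_a, agg$term_b), , drop = FALSE]
  } else {
    superedges <- empty_edges()[c("term_a", "term_b", "weight")]
  }
  structure(list(supernodes = supernodes,
                 superedges = canonical_edges(superedges),
                 level = 1L, policy = policy),
            class = "abstract_graph")
}

#' @export
print.abstract_graph <- function(x, ...) {
  cat(sprintf("<abstract_graph (%s): %d supernodes, %d superedges>\n",
              x$policy, nrow(x$supernodes), nrow(x$superedges)))
  invisible(x)
}

#' Deterministic force-directed layout with minimum node separation
#'
#' Runs a seeded Fruchterman–Reingold layout, then a deterministic
#' separation pass guaranteeing a minimum pairwise distance in scaled
#' pixels: violating pairs are pushed apart iteratively and, if violations
#' persist, nodes are snapped to free cells of the touch-target grid (which
#' always satisfies the minimum when the node count fits the view budget).
#' Positions are stored normalized to the unit square.
#'
#' @param x a `relationship_graph`, `goi` or `abstract_graph`.
#' @param view a [view_spec()] providing the pixel frame.
#' @param seed layout seed (default 7); identical inputs and seed yield
#'   identical positions.
#' @param min_sep minimum pairwise distance in pixels; defaults to the
#'   view's touch target.
#' @return An object of class `layout_graph`: `positions` data frame
#'   (`node`, `x`, `y` in `[0,1]`), `seed`, `min_sep`, `view`.
#' @export
layout_graph <- function(x, view, seed = 7L, min_sep = NULL) {
  stopifnot(inherits(view, "view_spec"))
  gf <- graph_frame(x)
  if (nrow(gf$nodes) == 0L) stop("empty graph")
  if (is.null(min_sep)) min_sep <- view$touch_target
  w <- view$width
  h <- view$height
  terms <- gf$nodes$term
  ig <- igraph::graph_from_data_frame(
    gf$edges[c("term_a", "term_b", "weight")],
    directed = FALSE, vertices = data.frame(name = terms))
  coords <- with_local_seed(seed, igraph::layout_with_fr(ig, niter = 500))
  px <- normalize01(coords[, 1]) * w
  py <- normalize01(coords[, 2]) * h
  sep <- separate_positions(px, py, w, h, min_sep, view$touch_target)
  structure(list(positions = data.frame(node = terms,
                                        x = sep$x / w, y = sep$y / h,
                                        stringsAsFactors = FALSE),
                 seed = as.integer(seed), min_sep = min_sep, view = view),
            class = "layout_graph")
}

normalize01 <- function(v, margin = 0.05) {
  rng <- range(v)
  if (diff(rng) < .Machine$double.eps) {
    return(rep(0.5, length(v)))
  }
  margin + (1 - 2 * margin) * (v - rng[1]) / diff(rng)
}

# Push-apart relaxation with a grid-snap fallback that makes the minimum
# separation a hard guarantee whenever enough grid cells exist.
separate_positions <- function(px, py, w, h, min_sep, cell, max_iter = 200L) {
  n <- length(px)
  if (n > 1L) {
    for (iter in seq_len(max_iter)) {
      d <- as.matrix(stats::dist(cbind(px, py)))
      diag(d) <- Inf
      viol <- which(d < min_sep, arr.ind = TRUE)
      viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
      if (nrow(viol) == 0L) break
      for (r in seq_len(nrow(viol))) {
        i <- viol[r, 1]; j <- viol[r, 2]
        dx <- px[j] - px[i]; dy <- py[j] - py[i]
        len <- sqrt(dx^2 + dy^2)
        if (len < .Machine$double.eps) {
          # coincident: deterministic split along x
          dx <- 1; dy <- 0; len <- 1
        }
        push <- (min_sep - len) / 2 + 0.5
        px[i] <- px[i] - push * dx / len; py[i] <- py[i] - push * dy / len
        px[j] <- px[j] + push * dx / len; py[j] <- py[j] + push * dy / len
      }
      px <- pmin(pmax(px, 0), w)
      py <- pmin(pmax(py, 0), h)
    }
    d <- as.matrix(stats::dist(cbind(px, py)))
    diag(d) <- Inf
    if (min(d) < min_sep) {
      snapped <- snap_to_grid(px, py, w, h, cell)
      if (is.null(snapped)) {
        warning("cannot guarantee minimum separation: ", n,
                " nodes exceed the view grid")
      } else {
        px <- snapped$x
        py <- snapped$y
      }
    }
  }
  list(x = px, y = py)
}

snap_to_grid <- function(px, py, w, h, cell) {
  nx <- floor(w / cell)
  ny <- floor(h / cell)
  if (length(px) > nx * ny) return(NULL)
  centers <- expand.grid(cx = (seq_len(nx) - 0.5) * cell,
                         cy = (seq_len(ny) - 0.5) * cell)
  free <- rep(TRUE, nrow(centers))
  out_x <- numeric(length(px))
  out_y <- numeric(length(py))
  for (i in seq_along(px)) {
    d2 <- (centers$cx - px[i])^2 + (centers$cy - py[i])^2
    d2[!free] <- Inf
    k <- which.min(d2)
    out_x[i] <- centers$cx[k]
    out_y[i] <- centers$cy[k]
    free[k] <- FALSE
  }
  list(x = out_x, y = out_y)
}

#' Filter a graph to a screen budget around the query
#'
#' Keeps the view's center node plus, breadth-first from the retained set,
#' the neighbours with the highest edge weight to the retained set, until
#' the view budget (`floor(w/t) * floor(h/t)` nodes) is reached; the induced
#' subgraph on the retained nodes is returned. Ties break lexicographically
#' on the candidate term so the result is deterministic.
#'
#' @param graph a `relationship_graph`.
#' @param view a [view_spec()] whose `center` is a node of `graph`.
#' @return A `relationship_graph` with at most `view_budget(view)` nodes,
#'   always containing the center.
#' @export
filter_view <- function(graph, view) {
  stopifnot(inherits(graph, "relationship_graph"), inherits(view, "view_spec"))
  center <- view$center
  if (is.null(center) || !(center %in% graph$nodes$term)) {
    stop("view center ", if (is.null(center)) "(unset)" else center,
         " is not a node of the graph")
  }
  budget <- view_budget(view)
  if (budget >= node_count(graph)) return(graph)
  retained <- center
  e <- graph$edges
  while (length(retained) < budget) {
    touches_a <- e$term_a %in% retained
    touches_b <- e$term_b %in% retained
    frontier <- touches_a != touches_b   # exactly one endpoint retained
    if (!any(frontier)) break
    cand <- ifelse(touches_a[frontier], e$term_b[frontier], e$term_a[frontier])
    wts <- e$weight[frontier]
    best <- tapply(wts, cand, max)
    pick <- names(best)[order(-best, names(best))][1]
    retained <- c(retained, pick)
  }
  induced_subgraph_rg(graph, retained)
}

#' Mix two node colours
#'
#' Channel-wise integer mean (floored) of two RGB triples; used to colour an
#' edge curve from its two end nodes.
#'
#' @param a,b integer RGB triples in `[0, 255]`.
#' @return Integer RGB triple.
#' @examples
#' mix_color(c(255, 0, 0), c(0, 255, 0))  # 127 127 0
#' @export
mix_color <- function(a, b) {
  a <- as.integer(a)
  b <- as.integer(b)
  if (length(a) != 3L || length(b) != 3L || anyNA(a) || anyNA(b) ||
      any(c(a, b) < 0L) || any(c(a, b) > 255L)) {
    stop("colours must be RGB triples with channels in [0, 255]")
  }
  (a + b) %/% 2L
}
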
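#' Serialize a graph view as an XML data stream
#'
#' The XML stream is the wire format delivered to the mobile client: a
#' `<goi>` root carrying the scale level and the query center, `<node>`
#' elements with label, category, colour and normalized layout position, and
#' `<edge>` elements with weight, optional sign, a mixed endpoint colour and
#' the supporting document ids/URLs as `<url>` children. The schema ships
#' with the package (`system.file("extdata", "goi.xsd", package =
#' "relgraph")`) and [parse_goi_xml()] validates against it.
#'
#' @param x a `relationship_graph`, `goi` or `abstract_graph`.
#' @param layout a [layout_graph()] covering every node of `x`.
#' @param path optional output file; when `NULL` the `xml2::xml_document`
#'   is returned.
#' @param level scale index (0 = full detail); defaults to the object's own
#'   level (0 for a GOI/relationship graph, 1 for an abstract graph).
#' @param center query term recorded on the root; defaults to the GOI
#'   center when `x` is a `goi`.
#' @return `path` (invisibly) when writing, else the XML document.
#' @export
serialize_goi_xml <- function(x, layout, path = NULL, level = NULL,
                              center = NULL) {
  stopifnot(inherits(layout, "layout_graph"))
  gf <- graph_frame(x)
  if (is.null(level)) level <- gf$level
  if (is.null(center) && inherits(x, "goi")) center <- x$center
  pos <- layout$positions
  missing <- setdiff(gf$nodes$term, pos$node)
  if (length(missing)) {
    stop("layout does not cover nodes: ", paste(missing, collapse = ", "))
  }
  pos_of <- function(term, axis) pos[[axis]][match(term, pos$node)]

  doc <- xml2::xml_new_root("goi", level = as.character(as.integer(level)))
  if (!is.null(center)) xml2::xml_set_attr(doc, "centre", center)
  for (i in seq_len(nrow(gf$nodes))) {
    nd <- gf$nodes[i, ]
    xml2::xml_add_child(doc, "node", id = nd$term, label = nd$label,
                        category = nd$category, colour = nd$color,
                        x = num_attr(pos_of(nd$term, "x")),
                        y = num_attr(pos_of(nd$term, "y")))
  }
  col_of <- stats::setNames(gf$nodes$color, gf$nodes$term)
  for (i in seq_len(nrow(gf$edges))) {
    ed <- gf$edges[i, ]
    mixed <- col_hex(mix_color(hex_col(col_of[[ed$term_a]]),
                               hex_col(col_of[[ed$term_b]])))
    e <- xml2::xml_add_child(doc, "edge", source = ed$term_a,
                             target = ed$term_b,
                             weight = num_attr(ed$weight), colour = mixed)
    if (!is.na(ed$sign)) xml2::xml_set_attr(e, "sign", ed$sign)
    for (u in ed$doc_ids[[1]]) xml2::xml_add_child(e, "url", u)
  }
  if (is.null(path)) return(doc)
  xml2::write_xml(doc, path)
  invisible(path)
}

# full-precision numeric attribute (exact double round trip)
num_attr <- function(v) sprintf("%.17g", v)

#' Parse a GOI XML stream
#'
#' Validates the document against the shipped XSD and reconstructs the
#' graph view.
#'
#' @param x file path, XML string, or `xml2::xml_document`.
#' @param validate validate against the shipped schema (default `TRUE`).
#' @return An object of class `goi_view`: `nodes` and `edges` data frames
#'   (as in the serialized graph), `positions`, `level` and `center`.
#' @export
parse_goi_xml <- function(x, validate = TRUE) {
  doc <- if (inherits(x, "xml_document")) x else {
    tryCatch(xml2::read_xml(x),
             error = function(e) stop("malformed GOI XML: ",
                                      conditionMessage(e)))
  }
  if (validate) {
    xsd <- xml2::read_xml(system.file("extdata", "goi.xsd",
                                      package = "relgraph"))
    ok <- xml2::xml_validate(doc, xsd)
    if (!ok) {
      stop("GOI XML fails schema validation: ",
           paste(attr(ok, "errors"), collapse = "; "))
    }
  }
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "goi") {
    stop("not a GOI stream: root element is <", xml2::xml_name(root), ">")
  }
  level <- as.integer(xml2::xml_attr(root, "level"))
  center <- xml2::xml_attr(root, "centre")
  if (is.na(center)) center <- NULL

  nd <- xml2::xml_find_all(root, "./node")
  nodes <- data.frame(
    term = xml2::xml_attr(nd, "id"),
    label = xml2::xml_attr(nd, "label"),
    category = xml2::xml_attr(nd, "category"),
    color = xml2::xml_attr(nd, "colour"),
    stringsAsFactors = FALSE)
  positions <- data.frame(
    node = nodes$term,
    x = as.numeric(xml2::xml_attr(nd, "x")),
    y = as.numeric(xml2::xml_attr(nd, "y")),
    stringsAsFactors = FALSE)

  eds <- xml2::xml_find_all(root, "./edge")
  edges <- data.frame(
    term_a = xml2::xml_attr(eds, "source"),
    term_b = xml2::xml_attr(eds, "target"),
    weight = as.numeric(xml2::xml_attr(eds, "weight")),
    sign = chr_to_sign(xml2::xml_attr(eds, "sign")),
    colour = xml2::xml_attr(eds, "colour"),
    stringsAsFactors = FALSE)
  edges$doc_ids <- lapply(eds, function(e) {
    xml2::xml_text(xml2::xml_find_all(e, "./url"))
  })
  structure(list(nodes = nodes, edges = edges, positions = positions,
                 level = level, center = center),
            class = "goi_view")
}

#' @export
print.goi_view <- function(x, ...) {
  cat(sprintf("<goi_view level=%d centre=%s: %d nodes, %d edges>\n",
              x$level, x$center %||% "(none)", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}
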
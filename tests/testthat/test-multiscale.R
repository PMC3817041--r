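test_that("view budget follows the touch-target grid formula", {
  expect_equal(view_budget(view_spec(1080, 1920, 96)), 11 * 20)
  expect_equal(view_budget(view_spec(480, 800, 96)), 5 * 8)
  expect_error(view_spec(0, 100), "width")
})

test_that("category abstraction collapses a bipartite graph to two groups", {
  ex <- simulate_personalization_example(5)
  ag <- abstract_graph(ex$graph, "category")
  expect_equal(nrow(ag$supernodes), 2)
  expect_equal(nrow(ag$superedges), 1)
  expect_equal(ag$superedges$weight, sum(ex$graph$edges$weight))
  expect_equal(ag$level, 1L)
  # representative of the condition group is its only member
  cond <- ag$supernodes[ag$supernodes$category == "condition", ]
  expect_equal(cond$label, "palpitations")
  expect_setequal(unlist(ag$supernodes$members), ex$graph$nodes$term)
})

test_that("singleton abstraction is isomorphic to the input", {
  g <- load_edge_table(fixture_path("table_obesity_edges.tsv"))
  ag <- abstract_graph(g, "singleton")
  expect_equal(nrow(ag$supernodes), node_count(g))
  expect_equal(nrow(ag$superedges), edge_count(g))
  expect_equal(sort(ag$supernodes$label), sort(g$nodes$term))
  expect_equal(sum(ag$superedges$weight), sum(g$edges$weight))
})

test_that("every policy conserves total cross-group weight", {
  g <- load_edge_table(fixture_path("table_cardio_edges.tsv"))
  for (policy in c("category", "density", "singleton")) {
    ag <- abstract_graph(g, policy)
    grp_of <- stats::setNames(rep(ag$supernodes$id,
                                  lengths(ag$supernodes$members)),
                              unlist(ag$supernodes$members))
    cross <- grp_of[g$edges$term_a] != grp_of[g$edges$term_b]
    expect_equal(sum(ag$superedges$weight), sum(g$edges$weight[cross]),
                 info = policy)
    # groups partition the node set
    expect_setequal(unlist(ag$supernodes$members), g$nodes$term)
    expect_equal(sum(lengths(ag$supernodes$members)), node_count(g))
  }
  expect_error(abstract_graph(g, "magic"))
})

test_that("parallel cross-group edges aggregate by summation", {
  A <- term_space(c("a1", "a2"), "A", "food")
  B <- term_space(c("b1", "b2"), "B", "condition")
  g <- build_relationship_graph(
    data.frame(term_a = c("a1", "a2"), term_b = c("b1", "b2"),
               weight = c(3, 4)), 0, A, B)
  ag <- abstract_graph(g, "category")
  expect_equal(ag$superedges$weight, 7)
})

test_that("layout is seed-deterministic, bounded and separated", {
  g <- load_edge_table(fixture_path("table_obesity_edges.tsv"))
  v <- view_spec(1080, 1920, 96)
  l1 <- layout_graph(g, v, seed = 7)
  l2 <- layout_graph(g, v, seed = 7)
  expect_identical(l1$positions, l2$positions)
  l3 <- layout_graph(g, v, seed = 8)
  expect_false(identical(l1$positions, l3$positions))

  expect_true(all(l1$positions$x >= 0 & l1$positions$x <= 1))
  expect_true(all(l1$positions$y >= 0 & l1$positions$y <= 1))
  px <- cbind(l1$positions$x * 1080, l1$positions$y * 1920)
  d <- as.matrix(stats::dist(px))
  diag(d) <- Inf
  expect_gte(min(d), l1$min_sep)
})

test_that("two coincident nodes get pushed to the minimum separation", {
  A <- term_space("a1", "A", "food")
  B <- term_space("b1", "B", "condition")
  g <- build_relationship_graph(
    data.frame(term_a = "a1", term_b = "b1", weight = 1), 0, A, B)
  l <- layout_graph(g, view_spec(480, 800, 96), seed = 1)
  px <- cbind(l$positions$x * 480, l$positions$y * 800)
  expect_gte(stats::dist(px)[1], l$min_sep)
})

test_that("a dense star still satisfies separation via the grid fallback", {
  ex <- simulate_personalization_example(2)
  v <- view_spec(1080, 1920, 96)
  l <- layout_graph(ex$goi, v, seed = 4)
  px <- cbind(l$positions$x * 1080, l$positions$y * 1920)
  d <- as.matrix(stats::dist(px))
  diag(d) <- Inf
  expect_gte(min(d), l$min_sep)
})

test_that("filter_view keeps the center and the heaviest reachable nodes", {
  ex <- simulate_personalization_example(9)
  g <- ex$graph
  v <- view_spec(480, 384, 96, center = "palpitations")  # budget 5*4 = 20
  fg <- filter_view(g, v)
  expect_equal(node_count(fg), 20)
  expect_true("palpitations" %in% fg$nodes$term)
  # star: retained leaves must be the 19 heaviest edges (sort oracle)
  top19 <- g$edges$term_a[order(-g$edges$weight)][1:19]
  expect_setequal(setdiff(fg$nodes$term, "palpitations"), top19)
  expect_equal(edge_count(fg), 19)
})

test_that("filter_view is the identity when the budget covers the graph", {
  g <- load_edge_table(fixture_path("table_obesity_edges.tsv"))
  v <- view_spec(1080, 1920, 96, center = "stroke")
  fg <- filter_view(g, v)
  expect_equal(node_count(fg), node_count(g))
  expect_equal(edge_count(fg), edge_count(g))
  expect_error(filter_view(g, view_spec(100, 100, 96, center = "zzz")),
               "not a node")
})

test_that("filter_view output stays connected for connected input", {
  ex <- simulate_personalization_example(4)
  fg <- filter_view(ex$graph, view_spec(300, 300, 96, center = "palpitations"))
  ig <- as_igraph(fg)
  expect_true(igraph::is_connected(ig))
  expect_lte(node_count(fg), view_budget(view_spec(300, 300, 96)))
})

test_that("mix_color floors the channel-wise mean", {
  expect_equal(mix_color(c(255, 0, 0), c(0, 255, 0)), c(127L, 127L, 0L))
  expect_equal(mix_color(c(10, 20, 30), c(10, 20, 30)), c(10L, 20L, 30L))
  expect_equal(mix_color(c(0, 0, 0), c(255, 255, 255)), c(127L, 127L, 127L))
  expect_error(mix_color(c(256, 0, 0), c(0, 0, 0)), "\\[0, 255\\]")
  expect_error(mix_color(c(-1, 0, 0), c(0, 0, 0)), "\\[0, 255\\]")
})

test_that("XML stream round-trips the full graph view", {
  w <- planted_world(c(5, 2, 9), noise = 2, seed = 31, n_a = 3, n_b = 1)
  assoc <- count_cooccurrences(w$corpus, w$space_a, w$space_b)
  g <- build_relationship_graph(assoc, 0)
  g$edges$sign <- c("positive", NA, "negative")
  v <- view_spec(1080, 1920, 96)
  lay <- layout_graph(g, v, seed = 7)
  f <- withr::local_tempfile(fileext = ".xml")
  serialize_goi_xml(g, lay, path = f, center = "condb01")
  back <- parse_goi_xml(f)

  expect_equal(back$level, 0L)
  expect_equal(back$center, "condb01")
  expect_equal(back$nodes$term, g$nodes$term)
  expect_equal(back$nodes$category, g$nodes$category)
  expect_equal(back$nodes$color, g$nodes$color)
  expect_equal(back$edges$term_a, g$edges$term_a)
  expect_equal(back$edges$weight, g$edges$weight)
  expect_equal(back$edges$sign, g$edges$sign)
  # supporting document ids survive as <url> children
  expect_equal(back$edges$doc_ids, g$edges$doc_ids, ignore_attr = TRUE)
  expect_equal(back$positions$x, lay$positions$x)
  expect_equal(back$positions$y, lay$positions$y)
  # edge colour is the channel mix of its endpoints
  expect_equal(back$edges$colour[1], "#664C00")  # mix of #009900 and #CC0000
})

test_that("XML serialization validates against the shipped schema", {
  g <- load_edge_table(fixture_path("table_obesity_edges.tsv"))
  lay <- layout_graph(g, view_spec(1080, 1920, 96), seed = 7)
  doc <- serialize_goi_xml(g, lay, center = "stroke")
  xsd <- xml2::read_xml(fixture_path("goi.xsd"))
  expect_true(xml2::xml_validate(doc, xsd))
  # abstract graphs serialize at their own level
  ag <- abstract_graph(g, "category")
  lag <- layout_graph(ag, view_spec(1080, 1920, 96), seed = 7)
  adoc <- serialize_goi_xml(ag, lag)
  expect_true(xml2::xml_validate(adoc, xsd))
  expect_equal(parse_goi_xml(adoc)$level, 1L)
})

test_that("empty and malformed XML are handled explicitly", {
  A <- term_space("a1", "A", "food")
  B <- term_space("b1", "B", "condition")
  empty <- build_relationship_graph(
    data.frame(term_a = character(0), term_b = character(0),
               weight = numeric(0)), 0, A, B)
  doc <- xml2::xml_new_root("goi", level = "0")
  view <- parse_goi_xml(doc)
  expect_equal(nrow(view$nodes), 0)
  expect_equal(nrow(view$edges), 0)

  f <- withr::local_tempfile(lines = "<goi level='0'><node id='x'/></goi>")
  expect_error(parse_goi_xml(f), "schema")
  f2 <- withr::local_tempfile(lines = "<goi level='0'><node")
  expect_error(parse_goi_xml(f2), "malformed")
  f3 <- withr::local_tempfile(lines = "<other/>")
  expect_error(parse_goi_xml(f3), "schema|root")
})

test_that("serializing with an incomplete layout fails loudly", {
  g <- load_edge_table(fixture_path("table_obesity_edges.tsv"))
  lay <- layout_graph(g, view_spec(1080, 1920, 96))
  lay$positions <- lay$positions[-1, ]
  expect_error(serialize_goi_xml(g, lay), "does not cover")
})
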
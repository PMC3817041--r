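# Shared fixtures built in code at test time.

fixture_path <- function(name) {
  system.file("extdata", name, package = "relgraph")
}

food_space <- function(terms = c("pepper", "milk", "yogurt", "oats",
                                 "soft drinks")) {
  term_space(terms, "foods", "food", c(0L, 153L, 0L))
}

condition_space <- function(terms = c("stroke", "diabetes",
                                      "high cholesterol", "arthritis")) {
  term_space(terms, "conditions", "condition", c(204L, 0L, 0L))
}

# a planted world of n_a x n_b single-token terms with given pair counts
planted_world <- function(counts, noise = 0L, seed = 1L,
                          n_a = NULL, n_b = NULL) {
  n <- length(counts)
  if (is.null(n_a)) n_a <- ceiling(sqrt(n))
  if (is.null(n_b)) n_b <- ceiling(n / n_a)
  stopifnot(n_a * n_b >= n)
  a_terms <- sprintf("fooda%02d", seq_len(n_a))
  b_terms <- sprintf("condb%02d", seq_len(n_b))
  grid <- expand.grid(term_a = a_terms, term_b = b_terms,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- grid[seq_len(n), ]
  pairs$count <- as.integer(counts)
  sa <- term_space(a_terms, "A", "food", c(0L, 153L, 0L))
  sb <- term_space(b_terms, "B", "condition", c(204L, 0L, 0L))
  spec <- planted_spec(pairs, noise_docs = noise, seed = seed)
  list(space_a = sa, space_b = sb, spec = spec,
       corpus = generate_synthetic_corpus(spec, sa, sb))
}

# tiny deterministic hand-built corpus over the default spaces
toy_corpus <- function() {
  corpus(list(
    document("d1", "Red pepper may reduce stroke risk."),
    document("d2", "Milk, yogurt: diabetes studies. Milk again!"),
    document("d3", "patients with high cholesterol drink milk"),
    document("d4", "nothing relevant here"),
    document("d5", "PEPPER and Stroke and milk")
  ))
}
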
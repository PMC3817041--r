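#' Planted co-occurrence specification
#'
#' Declares the ground truth for a synthetic corpus: for each cross-space
#' term pair, how many documents must contain both terms (and no other
#' cross-space pair), plus a number of noise documents containing terms from
#' at most one space.
#'
#' @param pairs data frame with columns `term_a`, `term_b`, `count`
#'   (non-negative integer target document counts).
#' @param noise_docs non-negative number of noise documents.
#' @param seed integer seed controlling document construction.
#' @return An object of class `planted_spec`.
#' @export
planted_spec <- function(pairs, noise_docs = 0L, seed = 7L) {
  stopifnot(is.data.frame(pairs),
            all(c("term_a", "term_b", "count") %in% names(pairs)))
  pairs$term_a <- normalize_term(pairs$term_a)
  pairs$term_b <- normalize_term(pairs$term_b)
  pairs$count <- as.integer(pairs$count)
  if (anyNA(pairs$count) || any(pairs$count < 0L)) {
    stop("pair counts must be non-negative integers")
  }
  if (anyDuplicated(pairs[c("term_a", "term_b")])) stop("duplicate pairs")
  if (noise_docs < 0) stop("noise_docs must be non-negative")
  structure(list(pairs = pairs, noise_docs = as.integer(noise_docs),
                 seed = as.integer(seed)),
            class = "planted_spec")
}

#' Generate a synthetic corpus with planted co-occurrence structure
#'
#' Emulates pooled meta-search result pages without network access. Each
#' planted pair `(a, b)` yields exactly `count` documents whose text contains
#' the phrase `a`, the phrase `b`, and filler tokens guaranteed to match no
#' term in either space; noise documents contain terms from at most one
#' space. The output is fully deterministic given `spec$seed`.
#'
#' @param spec a [planted_spec()]; every `term_a` must belong to `space_a`
#'   and every `term_b` to `space_b`.
#' @param space_a,space_b the two [term_space()] vocabularies.
#' @return A [corpus()]. Counting co-occurrences on it recovers
#'   `spec$pairs$count` exactly.
#' @export
generate_synthetic_corpus <- function(spec, space_a, space_b) {
  stopifnot(inherits(spec, "planted_spec"),
            inherits(space_a, "term_space"), inherits(space_b, "term_space"))
  bad_a <- setdiff(spec$pairs$term_a, space_a$terms)
  bad_b <- setdiff(spec$pairs$term_b, space_b$terms)
  if (length(bad_a) || length(bad_b)) {
    stop("planted terms not in their term space: ",
         paste(c(bad_a, bad_b), collapse = ", "))
  }
  with_local_seed(spec$seed, {
    filler <- filler_vocabulary(space_a, space_b)
    docs <- list()
    n <- 0L
    for (i in seq_len(nrow(spec$pairs))) {
      a <- spec$pairs$term_a[i]
      b <- spec$pairs$term_b[i]
      for (j in seq_len(spec$pairs$count[i])) {
        n <- n + 1L
        docs[[n]] <- document(sprintf("doc%05d", n),
                              planted_text(c(a, b), filler))
      }
    }
    for (j in seq_len(spec$noise_docs)) {
      n <- n + 1L
      # noise: filler only, or filler plus a single term from one space
      kind <- sample(c("none", "a", "b"), 1L)
      planted <- switch(kind,
        none = character(0),
        a = sample(space_a$terms, 1L),
        b = sample(space_b$terms, 1L))
      docs[[n]] <- document(sprintf("doc%05d", n), planted_text(planted, filler))
    }
    out <- corpus(docs)
    validate_planted(out, spec, space_a, space_b)
    out
  })
}

# Interleave the planted phrases with runs of filler tokens.
planted_text <- function(phrases, filler) {
  chunks <- replicate(length(phrases) + 1L,
                      paste(sample(filler, sample(3:8, 1L), replace = TRUE),
                            collapse = " "))
  if (length(phrases) == 0L) return(chunks[[1L]])
  body <- paste(as.vector(rbind(chunks[seq_along(phrases)], phrases)),
                collapse = " ")
  paste(body, chunks[length(chunks)])
}

# Filler tokens disjoint from every token of either term space, so a filler
# run can never complete a phrase match.
filler_vocabulary <- function(space_a, space_b, n = 60L) {
  reserved <- space_tokens(space_a, space_b)
  pool <- character(0)
  while (length(pool) < n) {
    cand <- paste0("zz", paste0(sample(letters, 5L, replace = TRUE),
                                collapse = ""))
    if (!(cand %in% reserved) && !(cand %in% pool)) pool <- c(pool, cand)
  }
  pool
}

# Re-match every generated document and fail loudly if the term spaces make
# the planted truth impossible (e.g. one phrase nested inside another
# creates an unplanted cross-space pair).
validate_planted <- function(corp, spec, space_a, space_b) {
  planted_n <- sum(spec$pairs$count)
  for (i in seq_len(planted_n)) {
    d <- corp$documents[[i]]
    ma <- match_terms(d, space_a)
    mb <- match_terms(d, space_b)
    if (length(ma) != 1L || length(mb) != 1L) {
      stop("planted document ", d$id, " matches terms {",
           paste(c(ma, mb), collapse = ", "),
           "}; term spaces with nested phrases cannot be planted exactly")
    }
  }
  for (i in seq_len(spec$noise_docs)) {
    d <- corp$documents[[planted_n + i]]
    if (length(match_terms(d, space_a)) > 0L &&
        length(match_terms(d, space_b)) > 0L) {
      stop("noise document ", d$id, " spans both spaces")
    }
  }
  invisible(corp)
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
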
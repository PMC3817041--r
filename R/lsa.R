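#' Term-document count matrix
#'
#' Occurrence counts of each vocabulary term (as a contiguous token phrase)
#' in each document. Unlike the co-occurrence counter, this records how
#' often a phrase occurs, since latent semantic analysis operates on raw
#' counts.
#'
#' @param corp a [corpus()].
#' @param vocabulary character vector of normalized terms (typically the
#'   union of the two term spaces).
#' @return Integer matrix, `length(vocabulary)` rows by `corp$size` columns,
#'   with term/document dimnames.
#' @export
term_document_matrix <- function(corp, vocabulary) {
  stopifnot(inherits(corp, "corpus"))
  vocabulary <- unique(normalize_term(vocabulary))
  phrases <- strsplit(vocabulary, " ", fixed = TRUE)
  m <- matrix(0L, nrow = length(vocabulary), ncol = corp$size,
              dimnames = list(vocabulary, corpus_ids(corp)))
  for (j in seq_len(corp$size)) {
    tok <- tokenize(corp$documents[[j]]$text)
    if (length(tok) == 0L) next
    m[, j] <- vapply(phrases, function(pt) {
      l <- length(pt)
      if (l > length(tok)) return(0L)
      starts <- which(tok == pt[1])
      starts <- starts[starts + l - 1L <= length(tok)]
      sum(vapply(starts, function(s) {
        all(tok[s:(s + l - 1L)] == pt)
      }, logical(1)))
    }, integer(1))
  }
  m
}

#' LSA baseline edge weights
#'
#' A standard latent-semantic-analysis edge weighting used as a comparison
#' baseline for the co-occurrence counter: truncated singular value
#' decomposition of the raw term-document count matrix; each term's latent
#' vector is `U_k %*% diag(d_k)` and a cross-space pair's weight is the
#' cosine similarity of the two latent vectors, clipped below at zero
#' (edge strengths are non-negative). No tf-idf or entropy weighting is
#' applied, keeping the baseline minimal and deterministic.
#'
#' @param corp a [corpus()].
#' @param space_a,space_b the two [term_space()] vocabularies.
#' @param dim latent dimension, between 1 and `min(|vocabulary|, |corpus|)`;
#'   default `min(100, rank - 1)` (at least 1).
#' @return Association data frame with columns `term_a`, `term_b`, `weight`
#'   (cosine in `[0, 1]`) for all cross-space pairs, sorted by
#'   `(term_a, term_b)`. Terms absent from the corpus get weight 0 with a
#'   warning.
#' @export
lsa_edge_weights <- function(corp, space_a, space_b, dim = NULL) {
  stopifnot(inherits(space_a, "term_space"), inherits(space_b, "term_space"))
  vocab <- c(space_a$terms, space_b$terms)
  m <- term_document_matrix(corp, vocab)
  sv <- svd(m)
  rank <- sum(sv$d > max(dim(m)) * .Machine$double.eps * max(sv$d, 0))
  if (is.null(dim)) dim <- max(1L, min(100L, rank - 1L))
  if (dim < 1L || dim > min(nrow(m), ncol(m))) {
    stop("dim must be in [1, ", min(nrow(m), ncol(m)), "]")
  }
  vecs <- sv$u[, seq_len(dim), drop = FALSE] %*%
    diag(sv$d[seq_len(dim)], nrow = dim)
  rownames(vecs) <- rownames(m)
  norms <- sqrt(rowSums(vecs^2))
  absent <- rownames(m)[rowSums(m) == 0L]
  if (length(absent)) {
    warning("terms absent from corpus get weight 0: ",
            paste(absent, collapse = ", "))
  }
  pairs <- expand.grid(term_a = space_a$terms, term_b = space_b$terms,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$term_a, pairs$term_b), , drop = FALSE]
  cosine <- mapply(function(a, b) {
    na <- norms[[a]]
    nb <- norms[[b]]
    if (na < .Machine$double.eps || nb < .Machine$double.eps) return(0)
    sum(vecs[a, ] * vecs[b, ]) / (na * nb)
  }, pairs$term_a, pairs$term_b)
  pairs$weight <- pmin(1, pmax(0, as.numeric(cosine)))
  rownames(pairs) <- NULL
  attr(pairs, "lsa_dim") <- dim
  pairs
}

#' Coefficient of variation of edge weights
#'
#' Population standard deviation divided by mean — the dispersion statistic
#' used to quantify how strongly an edge-weighting scheme differentiates
#' associations. LSA tends to produce near-uniform edge strengths (low
#' dispersion) while document co-occurrence counts preserve the intrinsic
#' differences (high dispersion).
#'
#' @param weights numeric vector of at least two non-negative weights with
#'   positive mean.
#' @return Non-negative scalar; 0 for perfectly uniform weights. Invariant
#'   under rescaling of all weights.
#' @examples
#' weight_dispersion(c(1, 3))  # sd 1, mean 2 -> 0.5
#' @export
weight_dispersion <- function(weights) {
  weights <- as.numeric(weights)
  if (length(weights) < 2L) stop("need at least two weights")
  if (any(weights < 0)) stop("weights must be non-negative")
  m <- mean(weights)
  if (m <= 0) stop("mean weight must be positive (all-zero weights)")
  sqrt(mean((weights - m)^2)) / m
}
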
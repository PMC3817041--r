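# Independent brute-force oracles. Deliberately written without reusing any
# package internals: their own tokenizer, their own phrase matcher, a plain
# O(docs x A x B) double loop.

oracle_tokens <- function(text) {
  tok <- unlist(strsplit(gsub("[^A-Za-z0-9]+", " ", tolower(text)), " ",
                         fixed = TRUE))
  tok[nzchar(tok)]
}

oracle_has_phrase <- function(tokens, phrase) {
  pt <- oracle_tokens(phrase)
  l <- length(pt)
  if (l == 0L || l > length(tokens)) return(FALSE)
  for (s in seq_len(length(tokens) - l + 1L)) {
    if (all(tokens[s:(s + l - 1L)] == pt)) return(TRUE)
  }
  FALSE
}

# counts matrix: rows = terms_a, cols = terms_b
oracle_cooccurrence_counts <- function(corp, terms_a, terms_b) {
  m <- matrix(0L, length(terms_a), length(terms_b),
              dimnames = list(terms_a, terms_b))
  for (d in corp$documents) {
    tok <- oracle_tokens(d$text)
    in_a <- vapply(terms_a, oracle_has_phrase, logical(1), tokens = tok)
    in_b <- vapply(terms_b, oracle_has_phrase, logical(1), tokens = tok)
    m[in_a, in_b] <- m[in_a, in_b] + 1L
  }
  m
}

# look up an inferred association weight (0 when the pair is absent)
assoc_weight <- function(assoc, a, b) {
  hit <- assoc$term_a == a & assoc$term_b == b
  if (any(hit)) assoc$weight[hit] else 0
}
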
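#' Term spaces
#'
#' A term space is one of the two controlled vocabularies whose cross pairs
#' define the relationship space: a named, coloured, ordered list of unique
#' lowercase terms or multi-word phrases (e.g. a food list and a
#' disease/condition list).
#'
#' @param terms character vector of terms or phrases (one or more tokens
#'   each). Terms are normalized: case-folded, whitespace collapsed.
#' @param name label for the space.
#' @param category semantic category, e.g. `"food"` or `"condition"`.
#' @param color integer RGB triple, each channel in `[0, 255]`, used for
#'   node colouring.
#' @return An object of class `term_space`.
#' @examples
#' term_space(c("pepper", "milk", "yogurt"), "foods", "food", c(0, 153, 0))
#' @export
term_space <- function(terms, name, category, color = c(127L, 127L, 127L)) {
  stopifnot(is.character(terms), length(name) == 1L, length(category) == 1L)
  color <- as.integer(color)
  if (length(color) != 3L || anyNA(color) || any(color < 0L | color > 255L)) {
    stop("color must be an RGB triple with channels in [0, 255]")
  }
  norm <- normalize_term(terms)
  norm <- norm[nzchar(norm)]
  if (length(norm) == 0L) stop("empty term space '", name, "'")
  dup <- unique(norm[duplicated(norm)])
  if (length(dup) > 0L) {
    stop("duplicate terms after normalization in '", name, "': ",
         paste(dup, collapse = ", "))
  }
  structure(
    list(name = name, category = category, color = color, terms = norm),
    class = "term_space"
  )
}

#' @export
print.term_space <- function(x, ...) {
  cat(sprintf("<term_space '%s' (%s): %d terms, colour #%02X%02X%02X>\n",
              x$name, x$category, length(x$terms),
              x$color[1], x$color[2], x$color[3]))
  invisible(x)
}

#' Read a term space from a plain-text file
#'
#' One term (or multi-word phrase) per line; blank lines are ignored; terms
#' are normalized (case-folded, whitespace collapsed) and must be unique
#' after normalization.
#'
#' @param path path to a UTF-8 text file, one term per line.
#' @inheritParams term_space
#' @return A [term_space].
#' @export
load_term_space <- function(path, name = basename(path), category = "term",
                            color = c(127L, 127L, 127L)) {
  if (!file.exists(path)) stop("term-space file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  term_space(lines[nzchar(trimws(lines))], name, category, color)
}

#' Write a term space back to a plain-text file
#'
#' Inverse of [load_term_space()]: writing and re-loading is a fixed point.
#'
#' @param space a [term_space].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_term_space <- function(space, path) {
  stopifnot(inherits(space, "term_space"))
  writeLines(space$terms, path, useBytes = TRUE)
  invisible(path)
}

# Case-fold and collapse runs of whitespace; the canonical term form.
normalize_term <- function(x) {
  gsub("\\s+", " ", trimws(tolower(x)))
}

# Split text into lowercase alphanumeric tokens (keyword-search semantics:
# punctuation and whitespace are separators, nothing else is interpreted).
tokenize <- function(text) {
  tok <- strsplit(tolower(text), "[^[:alnum:]]+")[[1]]
  tok[nzchar(tok)]
}

#' Match a term space against a document
#'
#' A term matches when its token sequence occurs contiguously in the
#' case-folded, tokenized document text. Presence semantics: a term matches
#' at most once regardless of how often it occurs.
#'
#' @param doc a [document()] (or anything with a `$text` field).
#' @param space a [term_space].
#' @return Character vector: the subset of `space$terms` present in the
#'   document, in term-space order.
#' @examples
#' d <- document("d1", "Red pepper may reduce stroke risk")
#' match_terms(d, term_space(c("pepper", "stroke", "milk"), "x", "food"))
#' @export
match_terms <- function(doc, space) {
  stopifnot(inherits(space, "term_space"))
  text <- if (is.character(doc)) doc else doc$text
  tok <- tokenize(text)
  if (length(tok) == 0L) return(character(0))
  hay <- paste0("\x01", paste(tok, collapse = "\x01"), "\x01")
  needles <- paste0("\x01", gsub(" ", "\x01", space$terms, fixed = TRUE), "\x01")
  space$terms[vapply(needles, grepl, logical(1), x = hay, fixed = TRUE)]
}

# All tokens appearing in any term of the given spaces.
space_tokens <- function(...) {
  unique(unlist(lapply(list(...), function(s) {
    unlist(strsplit(s$terms, " ", fixed = TRUE))
  })))
}
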
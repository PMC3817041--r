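#' Documents and corpora
#'
#' A corpus is the searchable text collection standing in for the pooled
#' result pages of a meta-search: an ordered list of documents, each with a
#' unique id, optional source URL and free text.
#'
#' @param id unique document identifier.
#' @param text document text.
#' @param url optional source URL (`NA` if unknown).
#' @return `document()` returns an object of class `document`.
#' @export
document <- function(id, text, url = NA_character_) {
  stopifnot(length(id) == 1L, length(text) == 1L)
  structure(list(id = as.character(id), url = as.character(url),
                 text = as.character(text)),
            class = "document")
}

#' @param documents list of [document()] objects with unique ids.
#' @rdname document
#' @return `corpus()` returns an object of class `corpus` with fields
#'   `documents` and `size`.
#' @export
corpus <- function(documents) {
  stopifnot(is.list(documents))
  ids <- vapply(documents, function(d) d$id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate document ids: ", paste(dup, collapse = ", "))
  }
  structure(list(documents = documents, size = length(documents)),
            class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus: %d documents>\n", x$size))
  invisible(x)
}

#' Read a corpus from disk
#'
#' Two on-disk layouts are supported: a directory of `.txt` files (file stem
#' becomes the document id) or a JSON-lines file with one object per line
#' carrying fields `id`, optional `url`, and `text`.
#'
#' @param path directory of `.txt` files, or a `.jsonl` file.
#' @return A [corpus()].
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    docs <- lapply(files, function(f) {
      document(sub("\\.txt$", "", basename(f)),
               paste(readLines(f, encoding = "UTF-8", warn = FALSE),
                     collapse = "\n"))
    })
    return(corpus(docs))
  }
  if (!file.exists(path)) stop("corpus path not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  docs <- lapply(lines[nzchar(lines)], function(l) {
    rec <- jsonlite::fromJSON(l)
    if (is.null(rec$id) || is.null(rec$text)) {
      stop("corpus JSON-lines record missing 'id' or 'text': ", substr(l, 1, 60))
    }
    document(rec$id, rec$text, if (is.null(rec$url)) NA_character_ else rec$url)
  })
  corpus(docs)
}

#' Write a corpus to disk
#'
#' @param x a [corpus()].
#' @param path output path; a directory (one `.txt` per document) unless
#'   `format = "jsonl"`.
#' @param format `"dir"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = c("dir", "jsonl")) {
  stopifnot(inherits(x, "corpus"))
  format <- match.arg(format)
  if (format == "dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (d in x$documents) {
      writeLines(d$text, file.path(path, paste0(d$id, ".txt")), useBytes = TRUE)
    }
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    for (d in x$documents) {
      rec <- list(id = d$id, text = d$text)
      if (!is.na(d$url)) rec$url <- d$url
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = TRUE)
    }
  }
  invisible(path)
}

corpus_ids <- function(x) vapply(x$documents, function(d) d$id, character(1))
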
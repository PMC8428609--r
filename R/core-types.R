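#' Registered entity types
#'
#' The five canonical biomedical entity types (`CellLine`, `Chemical`,
#' `Disease`, `Gene`, `Species`) are always registered; additional types can
#' be registered by name.
#'
#' @return `entity_types()` returns the character vector of registered names.
#' @export
entity_types <- function() .bioner$entity_types

#' @rdname entity_types
#' @param name non-empty character scalar; registering an existing name is a
#'   no-op.
#' @export
register_entity_type <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("entity type name must be a non-empty string")
  if (grepl("[[:space:]-]", name))
    stop("entity type name must not contain whitespace or '-': ", name)
  if (!name %in% .bioner$entity_types)
    .bioner$entity_types <- c(.bioner$entity_types, name)
  invisible(name)
}

#' @rdname entity_types
#' @export
is_entity_type <- function(name) name %in% .bioner$entity_types

#' Tokens, sentences and entity mentions
#'
#' All character offsets are 0-based and half-open: a span `(start, end)`
#' covers `substr(text, start + 1, end)` and `end > start` always holds.
#' Tokens carry offsets into the source document; a sentence stores its own
#' text plus its start offset in the document so token offsets can be mapped
#' to sentence-relative positions.
#'
#' @param text token / mention surface string (non-empty).
#' @param start,end 0-based half-open character offsets into the document.
#' @return `token()` returns a `ner_token`; `sentence()` a `ner_sentence`;
#'   `entity_mention()` a `ner_mention`.
#' @export
token <- function(text, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (!nzchar(text)) stop("token text must be non-empty")
  if (end <= start) stop("token span must satisfy end > start")
  if (end - start != nchar(text))
    stop("token span width must equal nchar(text)")
  structure(list(text = text, start = start, end = end), class = "ner_token")
}

#' @rdname token
#' @param tokens list of `ner_token` with strictly increasing, non-overlapping
#'   spans.
#' @param doc_id document identifier.
#' @param sent_text sentence text; if `NULL`, reconstructed by joining token
#'   texts with single spaces (token offsets are then recomputed from
#'   `sent_start`).
#' @param sent_start 0-based offset of the sentence within the document.
#' @export
sentence <- function(tokens, doc_id = "doc", sent_text = NULL, sent_start = 0L) {
  sent_start <- as.integer(sent_start)
  if (is.null(sent_text)) {
    # reconstruct text and offsets with single-space joining
    texts <- vapply(tokens, function(t) t$text, "")
    sent_text <- paste(texts, collapse = " ")
    pos <- sent_start
    tokens <- lapply(texts, function(tx) {
      tok <- token(tx, pos, pos + nchar(tx))
      pos <<- pos + nchar(tx) + 1L
      tok
    })
  }
  if (length(tokens)) {
    starts <- vapply(tokens, function(t) t$start, 0L)
    ends <- vapply(tokens, function(t) t$end, 0L)
    if (any(diff(starts) <= 0) || any(starts[-1] < ends[-length(ends)]))
      stop("token spans must be strictly increasing and non-overlapping")
    for (t in tokens) {
      rel <- t$start - sent_start
      if (substr(sent_text, rel + 1L, rel + nchar(t$text)) != t$text)
        stop("token text does not match sentence text at its offsets: ",
             t$text)
    }
  }
  structure(list(tokens = tokens, doc_id = doc_id, text = sent_text,
                 start = sent_start),
            class = "ner_sentence")
}

#' @rdname token
#' @param type a registered entity type name.
#' @export
entity_mention <- function(start, end, type, text) {
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop("mention span must satisfy end > start")
  if (!is.character(type) || !nzchar(type)) stop("mention type must be named")
  structure(list(start = start, end = end, type = type, text = text),
            class = "ner_mention")
}

#' @export
print.ner_sentence <- function(x, ...) {
  cat(sprintf("<sentence doc=%s tokens=%d> %s\n", x$doc_id,
              length(x$tokens), x$text))
  invisible(x)
}

#' @export
print.ner_mention <- function(x, ...) {
  cat(sprintf("<mention %s [%d,%d) \"%s\">\n", x$type, x$start, x$end, x$text))
  invisible(x)
}

n_tokens <- function(sent) length(sent$tokens)

token_starts <- function(sent) vapply(sent$tokens, function(t) t$start, 0L)
token_ends <- function(sent) vapply(sent$tokens, function(t) t$end, 0L)

# sentence-relative substring for a document-offset span
sentence_substr <- function(sent, start, end) {
  substr(sent$text, start - sent$start + 1L, end - sent$start)
}

# validate mention against sentence: range and exact text
validate_mention <- function(sent, m) {
  if (m$start < sent$start || m$end > sent$start + nchar(sent$text))
    stop(sprintf("mention [%d,%d) outside sentence range", m$start, m$end))
  got <- sentence_substr(sent, m$start, m$end)
  if (!identical(got, m$text))
    stop(sprintf("mention text mismatch: span holds \"%s\", mention says \"%s\"",
                 got, m$text))
  invisible(TRUE)
}

# TRUE where same-type mention pairs overlap (used by corpus validation)
same_type_overlaps <- function(mentions) {
  n <- length(mentions)
  if (n < 2L) return(NULL)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- mentions[[i]]; b <- mentions[[j]]
    if (a$type == b$type && max(a$start, b$start) < min(a$end, b$end))
      return(c(i, j))
  }
  NULL
}
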
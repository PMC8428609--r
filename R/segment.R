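#' Pluggable document segmentation
#'
#' A segmenter is a pair of procedures: `sentence_splitter(text)` returning a
#' matrix of 0-based half-open sentence spans, and `tokenizer(text)` doing
#' the same for tokens within a sentence. The default is deliberately simple
#' and rule-based (and abbreviation-blind): sentences end at `.`, `?` or `!`
#' followed by whitespace or end of text; tokens are maximal runs of
#' non-space characters with leading/trailing punctuation split into their
#' own tokens.
#'
#' @param sentence_splitter,tokenizer override either procedure; each takes a
#'   string and returns a 2-column integer matrix of `(start, end)` 0-based
#'   half-open spans, strictly increasing and non-overlapping.
#' @return a `segmenter`.
#' @export
default_segmenter <- function(sentence_splitter = NULL, tokenizer = NULL) {
  structure(list(
    sentence_splitter = sentence_splitter %||% rule_sentence_spans,
    tokenizer = tokenizer %||% rule_token_spans),
    class = "segmenter")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rule_sentence_spans <- function(text) {
  n <- nchar(text)
  ends <- integer(0)
  m <- gregexpr("[.?!](?=[[:space:]]|$)", text, perl = TRUE)[[1L]]
  if (m[1L] != -1L) ends <- as.integer(m)      # 1-based position of terminator
  bounds <- sort(unique(c(ends, n)))
  spans <- matrix(integer(0), ncol = 2L)
  start <- 1L
  for (e in bounds) {
    seg <- substr(text, start, e)
    lead <- attr(regexpr("^[[:space:]]*", seg), "match.length")
    trail <- attr(regexpr("[[:space:]]*$", seg), "match.length")
    if (nchar(seg) - lead - trail > 0L)
      spans <- rbind(spans, c(start + lead - 1L, e - trail))  # 0-based half-open
    start <- e + 1L
  }
  spans
}

rule_token_spans <- function(text) {
  spans <- matrix(integer(0), ncol = 2L)
  m <- gregexpr("[^[:space:]]+", text)[[1L]]
  if (m[1L] == -1L) return(spans)
  # POSIX bracket expression: ']' first so it is literal, no escapes needed
  punct <- "[][().,;:?!\"']"
  for (k in seq_along(m)) {
    a <- as.integer(m[k]); b <- a + attr(m, "match.length")[k] - 1L
    # split leading punctuation
    while (a < b && grepl(paste0("^", punct), substr(text, a, a)))
      { spans <- rbind(spans, c(a - 1L, a)); a <- a + 1L }
    # split trailing punctuation
    trail <- integer(0)
    while (b > a && grepl(paste0("^", punct), substr(text, b, b)))
      { trail <- c(b, trail); b <- b - 1L }
    spans <- rbind(spans, c(a - 1L, b))
    for (p in trail) spans <- rbind(spans, c(p - 1L, p))
  }
  spans
}

#' Segment raw text into tokenized sentences
#'
#' Character offsets of every token index into the original document, so
#' `substr(text, start + 1, end)` reproduces each token exactly.
#'
#' @param text document text.
#' @param seg a [default_segmenter()] (or a custom one).
#' @param doc_id document identifier recorded on each sentence.
#' @return list of [sentence()]; degenerate text yields an empty list.
#' @export
segment_document <- function(text, seg = default_segmenter(), doc_id = "doc") {
  if (!nzchar(text)) return(list())
  sent_spans <- seg$sentence_splitter(text)
  out <- list()
  for (i in seq_len(nrow(sent_spans))) {
    s0 <- sent_spans[i, 1L]; s1 <- sent_spans[i, 2L]
    stext <- substr(text, s0 + 1L, s1)
    tok_spans <- seg$tokenizer(stext)
    if (nrow(tok_spans) == 0L) next
    toks <- lapply(seq_len(nrow(tok_spans)), function(k) {
      a <- tok_spans[k, 1L] + s0; b <- tok_spans[k, 2L] + s0
      token(substr(text, a + 1L, b), a, b)
    })
    out[[length(out) + 1L]] <- sentence(toks, doc_id = doc_id,
                                        sent_text = stext, sent_start = s0)
  }
  out
}
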
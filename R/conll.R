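#' CoNLL column format description
#'
#' The canonical dialect: one token per line, whitespace-separated columns,
#' column 1 the token and the last column the tag, `#`-prefixed comment
#' lines, blank line between sentences, UTF-8, Unix newlines.
#'
#' @param token_col 1-based index of the token column.
#' @param tag_col 1-based index of the tag column, or `NA` for the last
#'   column on each line.
#' @param comment_prefix lines starting with this string are skipped.
#' @return a `conll_format`.
#' @export
conll_format <- function(token_col = 1L, tag_col = NA_integer_,
                         comment_prefix = "#") {
  token_col <- as.integer(token_col); tag_col <- as.integer(tag_col)
  if (token_col < 1L) stop("token_col must be >= 1")
  if (!is.na(tag_col) && (tag_col < 1L || tag_col == token_col))
    stop("tag_col must be >= 1 and differ from token_col")
  structure(list(token_col = token_col, tag_col = tag_col,
                 comment_prefix = comment_prefix),
            class = "conll_format")
}

#' Read / write CoNLL column files
#'
#' `read_conll()` reconstructs character offsets by joining tokens with
#' single spaces (no raw document text accompanies a column file), then
#' decodes the tag column into mentions. Ragged lines are rejected with
#' their line number; unknown tags are rejected by name.
#'
#' @param path file path.
#' @param fmt a [conll_format()].
#' @param scheme tag scheme of the file, `"BIOES"` or `"IOB2"`.
#' @param doc_prefix document-id prefix for reconstructed sentences.
#' @return list of records `list(sentence, mentions)`.
#' @export
read_conll <- function(path, fmt = conll_format(),
                       scheme = c("BIOES", "IOB2"), doc_prefix = NULL) {
  scheme <- match.arg(scheme)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(doc_prefix)) doc_prefix <- basename(path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  records <- list()
  cur_tok <- character(0); cur_tag <- character(0)
  # build sentence from token texts with single-space joining
  mk_record <- function(toks, tags, id) {
    pos <- 0L
    tok_objs <- lapply(toks, function(tx) {
      tk <- token(tx, pos, pos + nchar(tx))
      pos <<- pos + nchar(tx) + 1L
      tk
    })
    sent <- sentence(tok_objs, doc_id = id)
    mentions <- tags_to_spans(sent, tags, scheme)
    list(sentence = sent, mentions = unclass_attr(mentions))
  }
  nsent <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (nzchar(fmt$comment_prefix) && startsWith(ln, fmt$comment_prefix)) next
    if (!nzchar(trimws(ln))) {
      if (length(cur_tok)) {
        nsent <- nsent + 1L
        records[[nsent]] <- mk_record(cur_tok, cur_tag,
                                      paste0(doc_prefix, "#", nsent))
        cur_tok <- character(0); cur_tag <- character(0)
      }
      next
    }
    fields <- strsplit(trimws(ln), "[[:space:]]+")[[1L]]
    tag_col <- if (is.na(fmt$tag_col)) length(fields) else fmt$tag_col
    need <- max(fmt$token_col, tag_col)
    if (length(fields) < need || tag_col == fmt$token_col)
      stop(sprintf("line %d: expected >= %d whitespace-separated fields, got %d",
                   i, max(fmt$token_col, 2L), length(fields)))
    cur_tok <- c(cur_tok, fields[fmt$token_col])
    cur_tag <- c(cur_tag, fields[tag_col])
  }
  if (length(cur_tok)) {
    nsent <- nsent + 1L
    records[[nsent]] <- mk_record(cur_tok, cur_tag,
                                  paste0(doc_prefix, "#", nsent))
  }
  records
}

unclass_attr <- function(x) { attributes(x) <- NULL; as.list(x) }

#' @rdname read_conll
#' @param records list of `list(sentence, mentions)` (a corpus split).
#' @export
write_conll <- function(records, path, fmt = conll_format(),
                        scheme = c("BIOES", "IOB2")) {
  scheme <- match.arg(scheme)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (rec in records) {
    tags <- spans_to_tags(rec$sentence, rec$mentions, scheme)
    toks <- vapply(rec$sentence$tokens, function(t) t$text, "")
    writeLines(paste(toks, tags), con, sep = "\n", useBytes = TRUE)
    writeLines("", con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Read a corpus manifest
#'
#' A manifest is a JSON array of objects
#' `{name, entity_types, train, dev, test, scheme}` where `train`/`dev`/
#' `test` are CoNLL file paths relative to the manifest's directory.
#'
#' @param path manifest path.
#' @return list of [ner_corpus()].
#' @export
read_corpus_manifest <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  base <- dirname(path)
  lapply(entries, function(e) {
    scheme <- if (is.null(e$scheme)) "BIOES" else e$scheme
    rd <- function(p) {
      if (is.null(p)) return(list())
      read_conll(file.path(base, p), scheme = scheme)
    }
    ner_corpus(e$name, unlist(e$entity_types),
               train = rd(e$train), dev = rd(e$dev), test = rd(e$test))
  })
}
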
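#' Span / tag-sequence conversion
#'
#' Mentions are encoded one tag per token. Two schemes are supported:
#' `"BIOES"` (the internal standard; prefixes B/I/E/S plus `O`) and `"IOB2"`
#' (prefixes B/I plus `O`). Tag strings are `PREFIX-TYPENAME` or `O`.
#'
#' Mentions whose character boundaries do not coincide with token boundaries
#' are expanded outward to the smallest covering token run; such expansions
#' (and lenient repairs during decoding) are recorded in the `"warnings"`
#' attribute of the result, never silently dropped. Overlapping mentions are
#' rejected naming the offending pair.
#'
#' @param sent a [sentence()].
#' @param mentions list of [entity_mention()], non-overlapping.
#' @param scheme `"BIOES"` or `"IOB2"`.
#' @return `spans_to_tags()`: character vector of tags, one per token, with a
#'   `"warnings"` attribute (character, possibly empty). `tags_to_spans()`:
#'   list of `ner_mention`, with the same attribute.
#' @examples
#' s <- sentence(list(token("BRCA1", 0, 5), token("is", 6, 8),
#'                    token("mutated", 9, 16)))
#' spans_to_tags(s, list(entity_mention(0, 5, "Gene", "BRCA1")), "BIOES")
#' @export
spans_to_tags <- function(sent, mentions, scheme = c("BIOES", "IOB2")) {
  scheme <- match.arg(scheme)
  nt <- n_tokens(sent)
  tags <- rep("O", nt)
  warns <- character(0)
  if (length(mentions) == 0L) return(structure(tags, warnings = warns))
  starts <- token_starts(sent); ends <- token_ends(sent)
  ranges <- vector("list", length(mentions))
  for (k in seq_along(mentions)) {
    m <- mentions[[k]]
    validate_mention(sent, m)
    a <- which(ends > m$start)[1L]            # first token reaching past start
    b <- max(which(starts < m$end))           # last token starting before end
    if (is.na(a) || a > b)
      stop(sprintf("mention [%d,%d) covers no token", m$start, m$end))
    if (starts[a] != m$start || ends[b] != m$end)
      warns <- c(warns, sprintf(
        "mention %d [%d,%d) '%s' expanded to token span [%d,%d)",
        k, m$start, m$end, m$text, starts[a], ends[b]))
    ranges[[k]] <- c(a, b)
  }
  ord <- order(vapply(ranges, `[`, 0, 1L))
  ranges <- ranges[ord]; mentions <- mentions[ord]
  for (k in seq_along(ranges)) {
    if (k > 1L && ranges[[k]][1L] <= ranges[[k - 1L]][2L])
      stop(sprintf("overlapping mentions: [%d,%d) %s and [%d,%d) %s",
                   mentions[[k - 1L]]$start, mentions[[k - 1L]]$end,
                   mentions[[k - 1L]]$type,
                   mentions[[k]]$start, mentions[[k]]$end, mentions[[k]]$type))
    a <- ranges[[k]][1L]; b <- ranges[[k]][2L]; ty <- mentions[[k]]$type
    if (scheme == "BIOES") {
      if (a == b) tags[a] <- paste0("S-", ty)
      else {
        tags[a] <- paste0("B-", ty)
        if (b > a + 1L) tags[(a + 1L):(b - 1L)] <- paste0("I-", ty)
        tags[b] <- paste0("E-", ty)
      }
    } else {
      tags[a] <- paste0("B-", ty)
      if (b > a) tags[(a + 1L):b] <- paste0("I-", ty)
    }
  }
  structure(tags, warnings = warns)
}

parse_tag <- function(tag, scheme) {
  if (tag == "O") return(NULL)
  allowed <- if (scheme == "BIOES") c("B", "I", "E", "S") else c("B", "I")
  if (!grepl("^[A-Z]-.+$", tag))
    stop("unknown tag: '", tag, "'")
  prefix <- substr(tag, 1L, 1L)
  if (!prefix %in% allowed)
    stop("unknown tag: '", tag, "' (prefix not in scheme ", scheme, ")")
  list(prefix = prefix, type = substr(tag, 3L, nchar(tag)))
}

#' @rdname spans_to_tags
#' @param tags character vector, one tag per token.
#' @export
tags_to_spans <- function(sent, tags, scheme = c("BIOES", "IOB2")) {
  scheme <- match.arg(scheme)
  nt <- n_tokens(sent)
  if (length(tags) != nt)
    stop("length(tags) must equal the number of tokens")
  warns <- character(0)
  mentions <- list()
  open <- NULL  # list(type, a) token index where current span opened
  close_span <- function(b) {
    m <- entity_mention(sent$tokens[[open$a]]$start, sent$tokens[[b]]$end,
                        open$type,
                        sentence_substr(sent, sent$tokens[[open$a]]$start,
                                        sent$tokens[[b]]$end))
    mentions[[length(mentions) + 1L]] <<- m
    open <<- NULL
  }
  for (t in seq_len(nt)) {
    p <- parse_tag(tags[t], scheme)
    if (is.null(p)) {            # O
      if (!is.null(open)) {
        if (scheme == "BIOES")
          warns <- c(warns, sprintf("token %d: span closed by O without E/S", t))
        close_span(t - 1L)
      }
      next
    }
    if (!is.null(open) && (p$type != open$type || p$prefix %in% c("B", "S"))) {
      if (scheme == "BIOES" && p$type == open$type)
        warns <- c(warns, sprintf("token %d: %s begins before previous span closed",
                                  t, tags[t]))
      close_span(t - 1L)
    }
    if (is.null(open)) {
      if (p$prefix %in% c("I", "E"))
        warns <- c(warns, sprintf("token %d: orphan %s treated as span start",
                                  t, tags[t]))
      open <- list(type = p$type, a = t)
    }
    if (scheme == "BIOES" && p$prefix %in% c("E", "S")) close_span(t)
  }
  if (!is.null(open)) {
    if (scheme == "BIOES")
      warns <- c(warns, "sentence ends inside an unterminated span")
    close_span(nt)
  }
  structure(mentions, warnings = warns)
}

#' Tag inventory of a scheme for a set of entity types
#'
#' `O` first (so the deterministic Viterbi tie-break favours it), then the
#' prefixed tags per type in a fixed order.
#'
#' @param types character vector of entity type names.
#' @param scheme `"BIOES"` or `"IOB2"`.
#' @return character vector of tag strings.
#' @export
tag_inventory <- function(types, scheme = c("BIOES", "IOB2")) {
  scheme <- match.arg(scheme)
  prefixes <- if (scheme == "BIOES") c("B", "I", "E", "S") else c("B", "I")
  c("O", as.vector(t(outer(types, prefixes,
                           function(ty, p) paste0(p, "-", ty)))))
}
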
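#' Word embedding table with subword fallback
#'
#' A vocabulary of stored vectors plus hashed character n-gram bucket
#' vectors. An in-vocabulary word returns its stored vector exactly; an
#' out-of-vocabulary word returns the mean of the bucket vectors of the
#' character n-grams of the angle-bracket-padded word (`"<word>"`, all
#' n-gram lengths in `[n_min, n_max]`), so lookup is total over arbitrary
#' Unicode strings. Buckets are assigned with an FNV-1a hash over UTF-8
#' bytes modulo the bucket count. Lowercasing is off by default (gene
#' symbols are case-sensitive).
#'
#' @param dim vector dimension.
#' @param vocab optional named list/matrix of stored vectors (names = words).
#' @param n_min,n_max subword n-gram length range.
#' @param n_buckets number of hash buckets.
#' @param lowercase lowercase words before lookup.
#' @param seed RNG seed for bucket vector initialization.
#' @return a `word_embedding_table`.
#' @export
word_embedding_table <- function(dim = 16L, vocab = NULL, n_min = 3L,
                                 n_max = 4L, n_buckets = 2048L,
                                 lowercase = FALSE, seed = 1L) {
  dim <- as.integer(dim)
  if (!is.null(vocab)) {
    vocab <- do.call(rbind, lapply(vocab, as.numeric))
    if (ncol(vocab) != dim) stop("stored vectors must have length dim")
  }
  set.seed(seed)
  buckets <- matrix(runif(n_buckets * dim, -1, 1), n_buckets, dim)
  structure(list(dim = dim, vocab = vocab, n_min = as.integer(n_min),
                 n_max = as.integer(n_max), n_buckets = as.integer(n_buckets),
                 buckets = buckets, lowercase = lowercase),
            class = "word_embedding_table")
}

# 32-bit FNV-1a over UTF-8 bytes, computed in double precision; the multiply
# is split into 16-bit halves so every intermediate stays below 2^53 (exact)
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

bitwXor32 <- function(a, b) {
  # xor of a (< 2^32) with a byte, avoiding 32-bit signed overflow
  lo <- bitwXor(as.integer(a %% 65536), as.integer(b))
  a - (a %% 65536) + lo
}

char_ngrams <- function(word, n_min, n_max) {
  padded <- paste0("<", word, ">")
  cs <- strsplit(padded, "", fixed = TRUE)[[1L]]
  L <- length(cs)
  out <- character(0)
  for (n in n_min:n_max) {
    if (n > L) next
    for (i in seq_len(L - n + 1L))
      out <- c(out, paste(cs[i:(i + n - 1L)], collapse = ""))
  }
  out
}

#' Embed one word
#'
#' @param table a [word_embedding_table()].
#' @param word non-empty string.
#' @return numeric vector of length `table$dim`.
#' @export
embed_word <- function(table, word) {
  if (!nzchar(word)) stop("word must be non-empty")
  if (table$lowercase) word <- tolower(word)
  if (!is.null(table$vocab) && word %in% rownames(table$vocab))
    return(as.numeric(table$vocab[word, ]))
  grams <- char_ngrams(word, table$n_min, table$n_max)
  idx <- vapply(grams, function(g) fnv1a32(g) %% table$n_buckets, 0) + 1L
  colMeans(table$buckets[idx, , drop = FALSE])
}

#' Embedding stacks
#'
#' An ordered list of embedding sources; a sentence embeds to the row-wise
#' concatenation of each source's per-token vectors, in stack order. Two
#' source kinds exist: `word_embeddings(table)` (context-free lookup) and
#' `char_lm_embeddings(fwd, bwd)` (contextual, from a char-LM pair).
#'
#' @param ... embedding sources.
#' @return an `embedding_stack` with `$total_dim`.
#' @export
embedding_stack <- function(...) {
  sources <- list(...)
  if (length(sources) == 0L) stop("embedding stack must be non-empty")
  dims <- vapply(sources, function(s) s$dim, 0L)
  structure(list(sources = sources, total_dim = sum(dims)),
            class = "embedding_stack")
}

#' @rdname embedding_stack
#' @param table a [word_embedding_table()].
#' @export
word_embeddings <- function(table) {
  structure(list(kind = "word", table = table, dim = table$dim),
            class = "embedding_source")
}

#' @rdname embedding_stack
#' @param fwd,bwd forward / backward [char_lm()] models (equal hidden size).
#' @export
char_lm_embeddings <- function(fwd, bwd) {
  if (fwd$hidden_dim != bwd$hidden_dim)
    stop("forward and backward LMs must share hidden_dim")
  structure(list(kind = "char_lm", fwd = fwd, bwd = bwd,
                 dim = 2L * fwd$hidden_dim),
            class = "embedding_source")
}

source_matrix <- function(src, sent) {
  nt <- n_tokens(sent)
  if (src$kind == "char_lm") {
    m <- embed_tokens(src$fwd, src$bwd, sent)
  } else if (nt == 0L) {
    m <- matrix(0, 0L, src$dim)
  } else {
    m <- do.call(rbind, lapply(sent$tokens, function(t)
      embed_word(src$table, t$text)))
  }
  if (ncol(m) != src$dim)
    stop(sprintf("embedding source produced dim %d, declared %d",
                 ncol(m), src$dim))
  m
}

#' Embed a sentence through a stack
#'
#' @param stack an [embedding_stack()].
#' @param sent a [sentence()].
#' @return matrix `n_tokens x total_dim`; deterministic.
#' @export
embed_sentence <- function(stack, sent) {
  mats <- lapply(stack$sources, source_matrix, sent = sent)
  out <- do.call(cbind, mats)
  if (n_tokens(sent) == 0L) out <- matrix(0, 0L, stack$total_dim)
  out
}

#' Read a plain-text embedding table
#'
#' One `word v1 v2 ... vD` per line; an optional `N D` header line is
#' tolerated. Returns a [word_embedding_table()] whose vocabulary holds the
#' file's vectors (subword hashing still covers OOV words).
#'
#' @param path file path.
#' @param ... passed to [word_embedding_table()].
#' @export
read_word_embeddings <- function(path, ...) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  first <- strsplit(lines[1L], "[[:space:]]+")[[1L]]
  if (length(first) == 2L && !anyNA(suppressWarnings(as.numeric(first))))
    lines <- lines[-1L]
  parts <- strsplit(lines, "[[:space:]]+")
  words <- vapply(parts, `[`, "", 1L)
  vecs <- lapply(parts, function(p) as.numeric(p[-1L]))
  d <- length(vecs[[1L]])
  tab <- word_embedding_table(dim = d, ...)
  tab$vocab <- do.call(rbind, vecs)
  rownames(tab$vocab) <- words
  tab
}
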
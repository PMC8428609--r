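# Shared toy builders and independent oracles. Heavier objects (embedding
# stacks with trained char LMs) are memoised so test files share one copy.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# sentence from plain words (single-space joined, offsets from 0)
sent_words <- function(words, doc_id = "t") {
  pos <- 0L
  toks <- lapply(words, function(w) {
    tk <- token(w, pos, pos + nchar(w))
    pos <<- pos + nchar(w) + 1L
    tk
  })
  sentence(toks, doc_id = doc_id)
}

# mention covering tokens a..b of a sentence
tok_mention <- function(sent, a, b, type) {
  s <- sent$tokens[[a]]$start; e <- sent$tokens[[b]]$end
  entity_mention(s, e, type, substr(sent$text, s + 1L, e))
}

# random non-overlapping token-aligned mention set over `nt` tokens
random_mentions <- function(sent, types = c("Gene", "Disease")) {
  nt <- length(sent$tokens)
  out <- list()
  t <- 1L
  while (t <= nt) {
    if (runif(1) < 0.4) {
      len <- sample(1:min(3L, nt - t + 1L), 1L)
      out[[length(out) + 1L]] <- tok_mention(sent, t, t + len - 1L,
                                             sample(types, 1L))
      t <- t + len
    } else t <- t + 1L
  }
  out
}

random_sentence <- function(nt) {
  sent_words(replicate(nt, paste(sample(letters, sample(2:6, 1L),
                                        replace = TRUE), collapse = "")))
}

# ---- independent CRF oracle: exhaustive path enumeration -------------------
# scores computed with plain loops, no calls into the package's scoring code
enum_path_scores <- function(e, trans) {
  K <- ncol(e); Tn <- nrow(e)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  scores <- numeric(nrow(paths))
  for (r in seq_len(nrow(paths))) {
    p <- paths[r, ]
    s <- trans[K + 1L, p[1L]] + trans[p[Tn], K + 2L]
    for (t in seq_len(Tn)) s <- s + e[t, p[t]]
    if (Tn > 1L) for (t in seq_len(Tn - 1L)) s <- s + trans[p[t], p[t + 1L]]
    scores[r] <- s
  }
  list(paths = paths, scores = scores)
}

random_crf_instance <- function(max_T = 6L, max_K = 5L) {
  Tn <- sample(1:max_T, 1L); K <- sample(2:max_K, 1L)
  list(e = matrix(rnorm(Tn * K), Tn, K),
       trans = matrix(rnorm((K + 2L)^2), K + 2L, K + 2L))
}

# ---- shared toy embedding stacks -------------------------------------------
toy_chars <- paste(c(letters, LETTERS, 0:9, " .-"), collapse = "")

# cheap stack: random-init char LMs (8 hidden) + hashed words (8) — fast
toy_stack_small <- function() memo("stack_small", {
  v <- char_vocab(toy_chars)
  embedding_stack(
    char_lm_embeddings(char_lm(v, 8L, 8L, "forward", seed = 101L),
                       char_lm(v, 8L, 8L, "backward", seed = 102L)),
    word_embeddings(word_embedding_table(8L, seed = 103L)))
})

# acceptance-scale stack: char LMs (32 hidden) trained on template text
toy_stack_trained <- function() memo("stack_trained", {
  txt <- generate_lm_text("template", 8000L, seed = 41L,
                          spec = generator_spec(seed = 41L))
  fwd <- train_lm(txt, hidden_dim = 32L, char_dim = 16L, epochs = 5L,
                  direction = "forward", seed = 41L)
  bwd <- train_lm(txt, hidden_dim = 32L, char_dim = 16L, epochs = 5L,
                  direction = "backward", seed = 41L)
  embedding_stack(char_lm_embeddings(fwd, bwd),
                  word_embeddings(word_embedding_table(16L, seed = 41L)))
})

shared_gene_dict <- function() memo("gene_dict",
                                    list(Gene = entity_dictionary("Gene",
                                                                  seed = 5L)))
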
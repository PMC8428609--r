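#' Synthetic entity dictionaries
#'
#' Deterministic, type-disjoint surface-form inventories emulating the shape
#' of real biomedical names: gene symbols are uppercase letters plus digits,
#' chemicals are syllabic with drug-like suffixes, diseases carry clinical
#' suffixes, species are two-token binomials, cell lines are
#' letters-hyphen-digits codes. Extension types get a generic syllabic
#' pattern carrying the type name. Disjointness across types is structural.
#'
#' @param type entity type name.
#' @param n number of surface forms.
#' @param seed RNG seed.
#' @return character vector of `n` unique surface forms.
#' @export
entity_dictionary <- function(type, n = 24L, seed = 1L) {
  set.seed(seed + nchar(type) * 131L)
  syll <- function(k) paste(vapply(seq_len(k), function(i)
    paste0(sample(c("b","c","d","f","g","l","m","n","p","r","s","t","v","z"), 1L),
           sample(c("a","e","i","o","u"), 1L)), ""), collapse = "")
  gen <- switch(type,
    Gene = function() paste0(
      paste(sample(LETTERS, sample(3:4, 1L), replace = TRUE), collapse = ""),
      sample(1:9, 1L)),
    Chemical = function() paste0(syll(sample(2:3, 1L)),
                                 sample(c("ol", "ine", "ate", "ide", "in"), 1L)),
    Disease = function() paste0(syll(sample(2:3, 1L)),
                                sample(c("itis", "oma", "pathy", "osis"), 1L)),
    Species = function() paste0(
      paste0(toupper(substr(syll(1L), 1L, 1L)), substr(s <- syll(3L), 2L, 6L)),
      " ", syll(sample(2:3, 1L))),
    CellLine = function() paste0(
      paste(sample(LETTERS, sample(2:3, 1L), replace = TRUE), collapse = ""),
      "-", sample(1:999, 1L)),
    function() paste0(tolower(type), syll(2L), sample(1:99, 1L)))
  out <- character(0)
  while (length(out) < n) out <- unique(c(out, gen()))
  out[seq_len(n)]
}

type_keyword <- function(type) {
  switch(type, Gene = "gene", Chemical = "compound", Disease = "disease",
         Species = "species", CellLine = "cells", "entity")
}

default_templates <- function() list(
  c("expression", "of", "<ENT>", "was", "elevated", "in", "tumor", "samples", "."),
  c("we", "observed", "that", "<ENT>", "regulates", "cell", "growth", "."),
  c("treatment", "with", "<ENT>", "reduced", "proliferation", "in", "vitro", "."),
  c("mutations", "in", "<ENT>", "and", "<ENT>", "were", "detected", "."),
  c("analysis", "revealed", "increased", "levels", "of", "<ENT>", "."),
  c("patients", "carrying", "<ENT>", "showed", "poor", "outcome", "."),
  c("the", "role", "of", "<ENT>", "remains", "unclear", "."),
  c("<ENT>", "was", "associated", "with", "response", "to", "therapy", "."),
  c("binding", "of", "<ENT>", "to", "<ENT>", "was", "confirmed", "."),
  c("samples", "positive", "for", "<ENT>", "were", "excluded", "."))

slot_fillers <- c("it", "this", "control", "baseline", "placebo")

#' Specification of a synthetic corpus
#'
#' States the world the generator renders: per-type surface dictionaries,
#' sentence templates with entity slots, split sizes, entity density (the
#' probability a slot is filled with an entity rather than a plain filler
#' word), and two annotation-convention dials that emulate divergent gold
#' standards across real corpora: `include_trailing_keyword` (the gold span
#' does or does not swallow a trailing type keyword such as "... gene") and
#' `boundary_jitter` (0 or 1: gold boundaries end one character inside the
#' token, as when annotators exclude a plural "s"). `char_noise_rate`
#' corrupts characters of non-entity words only, so gold offsets always
#' reproduce the mention text exactly. All randomness flows from `seed`
#' through a named stream per split, so splits are independently
#' reproducible.
#'
#' @param entity_types types to annotate.
#' @param dictionaries named list of surface-form vectors; defaults to
#'   [entity_dictionary()] per type.
#' @param templates list of token-vector templates with `"<ENT>"` slots.
#' @param n_train,n_dev,n_test split sizes.
#' @param entity_density slot-fill probability in `[0, 1]`.
#' @param keyword_rate probability an entity is rendered with its trailing
#'   type keyword token.
#' @param include_trailing_keyword convention flag (see above).
#' @param boundary_jitter 0 or 1 characters.
#' @param jitter_rate probability a mention is jittered when
#'   `boundary_jitter == 1`.
#' @param char_noise_rate per-character corruption rate of filler words.
#' @param seed master seed.
#' @param name corpus name.
#' @return a `generator_spec`.
#' @export
generator_spec <- function(entity_types = "Gene", dictionaries = NULL,
                           templates = default_templates(), n_train = 200L,
                           n_dev = 50L, n_test = 100L, entity_density = 0.7,
                           keyword_rate = 0.5,
                           include_trailing_keyword = FALSE,
                           boundary_jitter = 0L, jitter_rate = 0.3,
                           char_noise_rate = 0, seed = 1L,
                           name = "synthetic") {
  stopifnot(entity_density >= 0, entity_density <= 1,
            char_noise_rate >= 0, char_noise_rate <= 1,
            boundary_jitter %in% c(0L, 1L))
  if (is.null(dictionaries))
    dictionaries <- stats::setNames(
      lapply(entity_types, function(ty) entity_dictionary(ty, seed = seed)),
      entity_types)
  for (ty in entity_types)
    if (length(dictionaries[[ty]]) == 0L)
      stop("empty dictionary for requested type ", ty)
  structure(list(entity_types = entity_types, dictionaries = dictionaries,
                 templates = templates, n_train = as.integer(n_train),
                 n_dev = as.integer(n_dev), n_test = as.integer(n_test),
                 entity_density = entity_density, keyword_rate = keyword_rate,
                 include_trailing_keyword = include_trailing_keyword,
                 boundary_jitter = as.integer(boundary_jitter),
                 jitter_rate = jitter_rate,
                 char_noise_rate = char_noise_rate, seed = as.integer(seed),
                 name = name),
            class = "generator_spec")
}

noise_word <- function(word, rate) {
  if (rate <= 0) return(word)
  cs <- strsplit(word, "", fixed = TRUE)[[1L]]
  hit <- runif(length(cs)) < rate & grepl("[a-z]", cs)
  cs[hit] <- sample(letters, sum(hit), replace = TRUE)
  paste(cs, collapse = "")
}

render_sentence <- function(spec, id) {
  tpl <- spec$templates[[sample(length(spec$templates), 1L)]]
  words <- character(0)
  # mention plan: token index of name, n extra tokens in span, chars trimmed
  plan <- list()
  for (item in tpl) {
    if (item == "<ENT>") {
      if (runif(1L) < spec$entity_density) {
        ty <- if (length(spec$entity_types) == 1L) spec$entity_types
              else sample(spec$entity_types, 1L)
        name <- sample(spec$dictionaries[[ty]], 1L)
        name_toks <- strsplit(name, " ", fixed = TRUE)[[1L]]
        jit <- spec$boundary_jitter == 1L && runif(1L) < spec$jitter_rate
        if (jit)
          name_toks[length(name_toks)] <-
            paste0(name_toks[length(name_toks)], "s")
        kw <- runif(1L) < spec$keyword_rate
        first <- length(words) + 1L
        words <- c(words, name_toks)
        extra <- 0L; trim <- if (jit) 1L else 0L
        if (kw) {
          words <- c(words, type_keyword(ty))
          if (spec$include_trailing_keyword) { extra <- 1L; trim <- 0L }
        }
        plan[[length(plan) + 1L]] <-
          list(first = first, last = length(words) - (if (kw && extra == 0L) 1L else 0L),
               type = ty, trim = trim)
      } else {
        words <- c(words, sample(slot_fillers, 1L))
      }
    } else {
      words <- c(words, noise_word(item, spec$char_noise_rate))
    }
  }
  lens <- nchar(words)
  starts <- cumsum(c(0L, head(lens, -1L) + 1L))
  toks <- lapply(seq_along(words),
                 function(i) token(words[i], starts[i], starts[i] + lens[i]))
  sent <- sentence(toks, doc_id = id)
  mentions <- lapply(plan, function(p) {
    a <- starts[p$first]
    b <- starts[p$last] + lens[p$last] - p$trim
    entity_mention(a, b, p$type, substr(sent$text, a + 1L, b))
  })
  list(sentence = sent, mentions = mentions, source = spec$name)
}

derive_seed <- function(seed, k) as.integer((seed * 1000003 + k * 7919) %% 2147483647)

#' Generate a synthetic annotated corpus
#'
#' @param spec a [generator_spec()].
#' @return a [ner_corpus()]; identical across runs for the same spec.
#' @export
generate_corpus <- function(spec) {
  mk_split <- function(n, k) {
    set.seed(derive_seed(spec$seed, k))
    lapply(seq_len(n), function(i) render_sentence(spec, sprintf("%s-%d-%d",
                                                                 spec$name, k, i)))
  }
  ner_corpus(spec$name, spec$entity_types,
             train = mk_split(spec$n_train, 1L),
             dev = mk_split(spec$n_dev, 2L),
             test = mk_split(spec$n_test, 3L))
}

#' Generate raw text for language-model training
#'
#' Three styles: `periodic` repeats a motif (a deterministic source whose
#' per-character entropy after one character of context is zero), `markov`
#' samples a first-order chain with a known transition matrix (attached as
#' attributes `"transition"` and `"alphabet"` so cross-entropy lower bounds
#' are computable), `template` renders synthetic corpus sentences so the LM
#' sees the entity dictionaries in context.
#'
#' @param style `"periodic"`, `"markov"` or `"template"`.
#' @param length output length in characters.
#' @param seed RNG seed.
#' @param motif periodic motif.
#' @param alphabet markov alphabet.
#' @param transition markov row-stochastic matrix (default: a circulant with
#'   rows `(0.4, 0.3, 0.2, 0.1)` over a 4-letter alphabet).
#' @param spec [generator_spec()] for the template style.
#' @return a string of `length` characters.
#' @export
generate_lm_text <- function(style = c("periodic", "markov", "template"),
                             length = 10000L, seed = 1L, motif = "ab",
                             alphabet = c("a", "b", "c", "d"),
                             transition = NULL, spec = generator_spec()) {
  style <- match.arg(style)
  if (length <= 0L) stop("length must be positive")
  if (style == "periodic") {
    out <- substr(strrep(motif, ceiling(length / nchar(motif))), 1L, length)
    return(out)
  }
  if (style == "markov") {
    k <- base::length(alphabet)
    if (is.null(transition)) {
      transition <- matrix(0, k, k)
      base_row <- rev(sort(seq_len(k) / sum(seq_len(k))))
      for (i in seq_len(k)) transition[i, ] <-
        base_row[((seq_len(k) - i) %% k) + 1L]
    }
    stopifnot(all(abs(rowSums(transition) - 1) < 1e-12))
    set.seed(seed)
    idx <- integer(length)
    idx[1L] <- sample(k, 1L)
    for (t in seq_len(length - 1L))
      idx[t + 1L] <- sample(k, 1L, prob = transition[idx[t], ])
    out <- paste(alphabet[idx], collapse = "")
    attr(out, "transition") <- transition
    attr(out, "alphabet") <- alphabet
    return(out)
  }
  set.seed(seed)
  parts <- character(0); total <- 0L
  while (total < length) {
    s <- render_sentence(spec, "lm")$sentence$text
    parts <- c(parts, s)
    total <- total + nchar(s) + 1L
  }
  substr(paste(parts, collapse = " "), 1L, length)
}
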
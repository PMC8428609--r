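#' Annotated NER corpora
#'
#' A corpus bundles train/dev/test splits. Each split is a list of records
#' `list(sentence = <ner_sentence>, mentions = <list of ner_mention>,
#' source = <corpus name>)`; `source` carries per-sentence provenance through
#' merges. Validation enforces that every mention's type belongs to the
#' corpus's entity type set, lies inside its sentence, reproduces the
#' sentence text at its offsets, and that gold mentions of the *same* type
#' never overlap (different-type overlaps are allowed because tagging models
#' are per-type).
#'
#' @param name corpus name (unique within a pool).
#' @param entity_types character vector of annotated types; unseen names are
#'   registered.
#' @param train,dev,test split record lists (see above; `source` is filled in
#'   when missing).
#' @return a `ner_corpus`.
#' @export
ner_corpus <- function(name, entity_types, train = list(), dev = list(),
                       test = list()) {
  stopifnot(is.character(name), nzchar(name), length(entity_types) >= 1L)
  for (ty in entity_types) register_entity_type(ty)
  fix_split <- function(split) {
    lapply(split, function(rec) {
      stopifnot(inherits(rec$sentence, "ner_sentence"))
      for (m in rec$mentions) {
        if (!m$type %in% entity_types)
          stop(sprintf("mention type %s not in corpus entity types (%s)",
                       m$type, paste(entity_types, collapse = ", ")))
        validate_mention(rec$sentence, m)
      }
      ov <- same_type_overlaps(rec$mentions)
      if (!is.null(ov))
        stop(sprintf("overlapping same-type gold mentions (%d, %d) in '%s'",
                     ov[1L], ov[2L], rec$sentence$text))
      if (is.null(rec$source)) rec$source <- name
      rec
    })
  }
  structure(list(name = name, entity_types = entity_types,
                 train = fix_split(train), dev = fix_split(dev),
                 test = fix_split(test)),
            class = "ner_corpus")
}

#' @export
print.ner_corpus <- function(x, ...) {
  nm <- function(split) sum(vapply(split, function(r) length(r$mentions), 0L))
  cat(sprintf(
    "<ner_corpus '%s' types=[%s] train=%d/%d dev=%d/%d test=%d/%d (sent/mentions)>\n",
    x$name, paste(x$entity_types, collapse = ","),
    length(x$train), nm(x$train), length(x$dev), nm(x$dev),
    length(x$test), nm(x$test)))
  invisible(x)
}

count_mentions <- function(split, type = NULL) {
  sum(vapply(split, function(r) {
    if (is.null(type)) length(r$mentions)
    else sum(vapply(r$mentions, function(m) m$type == type, FALSE))
  }, 0L))
}

filter_split_type <- function(split, etype) {
  lapply(split, function(rec) {
    rec$mentions <- Filter(function(m) m$type == etype, rec$mentions)
    rec
  })
}

#' Merge corpora for one entity type (cross-corpus training set)
#'
#' Train splits are concatenated, as are dev splits; a corpus with no dev
#' split donates a seeded 10% slice of its train split (moved, not copied).
#' Test splits are never merged: they are kept per source corpus under
#' `$test_by_corpus` so evaluation stays per-corpus. Mentions of other types
#' are dropped; the dropped count per corpus is attached as attribute
#' `"dropped"`.
#'
#' @param corpora non-empty list of `ner_corpus`, each annotating `etype`.
#' @param etype entity type to keep.
#' @param dev_fraction,seed control the dev slice donated by corpora that
#'   lack one.
#' @return a `ner_corpus` named `merged-<etype>` with `$test_by_corpus`.
#' @export
merge_for_type <- function(corpora, etype, dev_fraction = 0.1, seed = 1L) {
  if (length(corpora) == 0L) stop("empty corpus list")
  for (co in corpora)
    if (!etype %in% co$entity_types)
      stop(sprintf("corpus '%s' does not annotate type %s", co$name, etype))
  train <- list(); dev <- list(); test_by_corpus <- list()
  dropped <- integer(0)
  for (co in corpora) {
    tr <- filter_split_type(co$train, etype)
    dv <- filter_split_type(co$dev, etype)
    dropped[co$name] <- (count_mentions(co$train) + count_mentions(co$dev)) -
      (count_mentions(tr) + count_mentions(dv))
    if (length(dv) == 0L && length(tr) > 0L) {
      k <- max(1L, round(dev_fraction * length(tr)))
      idx <- local({ set.seed(seed); sample(seq_along(tr), k) })
      dv <- tr[idx]; tr <- tr[-idx]
    }
    train <- c(train, tr)
    dev <- c(dev, dv)
    test_by_corpus[[co$name]] <- filter_split_type(co$test, etype)
  }
  out <- ner_corpus(paste0("merged-", etype), etype, train = train, dev = dev)
  out$test_by_corpus <- test_by_corpus
  attr(out, "dropped") <- dropped
  out
}

#' Remove held-out corpora from a pool by name
#'
#' @param pool list of `ner_corpus`.
#' @param held_out character vector of corpus names to exclude; every name
#'   must exist in the pool.
#' @return the pool without the named corpora (a warning if empty).
#' @export
remove_corpora <- function(pool, held_out) {
  nms <- vapply(pool, function(co) co$name, "")
  missing <- setdiff(held_out, nms)
  if (length(missing))
    stop("unknown corpus name(s): ", paste(missing, collapse = ", "))
  out <- pool[!nms %in% held_out]
  if (length(out) == 0L) warning("all corpora removed; pool is empty")
  out
}
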
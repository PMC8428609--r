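#' NER training configuration
#'
#' Plain SGD with a decay-on-plateau schedule: after `patience` epochs
#' without improvement of dev micro-F1 the learning rate is multiplied by
#' `lr_decay_factor`; training stops at the epoch limit or once the learning
#' rate falls below `min_lr`. The checkpoint with the best dev F1 is
#' returned.
#'
#' @param epochs maximum epochs.
#' @param batch_size sentences per parameter update (gradients averaged).
#' @param learning_rate initial SGD step size.
#' @param lr_decay_factor multiplicative decay in `(0, 1)`.
#' @param patience epochs without dev improvement before decay (`>= 1`).
#' @param min_lr stop threshold.
#' @param clip global gradient-norm clip.
#' @param seed run seed (initialization and batch shuffling).
#' @param checkpoint_dir optional directory for the training run artifacts
#'   (config snapshot, JSON-lines epoch log, best checkpoint).
#' @return a `train_config`.
#' @export
train_config <- function(epochs = 40L, batch_size = 8L, learning_rate = 1,
                         lr_decay_factor = 0.5, patience = 3L,
                         min_lr = 1e-3, clip = 5, seed = 1L,
                         checkpoint_dir = NULL) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            lr_decay_factor > 0, lr_decay_factor < 1, patience >= 1L,
            min_lr > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 patience = as.integer(patience), min_lr = min_lr,
                 clip = clip, seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir),
            class = "train_config")
}

# gold tag index sequence for a record
gold_indices <- function(model, rec) {
  tags <- spans_to_tags(rec$sentence, rec$mentions, model$scheme)
  tag_index(model$tag_dict, as.character(tags))
}

# cache embedding matrices for a split (stack is frozen during NER training)
embed_split <- function(stack, split) {
  lapply(split, function(rec) embed_sentence(stack, rec$sentence))
}

micro_f1_on <- function(model, records, cache = NULL,
                        protocol = match_protocol("exact_tolerant", 0L)) {
  preds <- lapply(seq_along(records), function(i)
    predict_mentions(model, records[[i]]$sentence,
                     X = if (is.null(cache)) NULL else cache[[i]]))
  evaluate_predictions(records, preds, protocol)$micro$f1
}

#' Train a BiLSTM-CRF tagger on one corpus
#'
#' Minimizes the mean per-sentence CRF negative log-likelihood by plain SGD
#' (embeddings frozen; encoder, projection and transitions updated). After
#' each epoch the dev-split micro-F1 (strict span matching) is computed for
#' model selection and the plateau schedule of the [train_config()]. Fully
#' reproducible given `cfg$seed`. The sentences presented to the optimizer
#' are audited: the returned log carries a leakage audit proving no test
#' sentence was trained on.
#'
#' @param corpus a [ner_corpus()] with a non-empty train split.
#' @param model a [tagger_model()] whose tag dictionary covers the corpus's
#'   entity types.
#' @param cfg a [train_config()].
#' @param quiet suppress per-epoch messages.
#' @return `list(model, log)` where `log` is a data.frame
#'   `(epoch, lr, train_loss, dev_f1)` with attributes `best_dev_f1` and
#'   `audit` (the split labels of all optimizer-visited sentences).
#' @export
train_ner <- function(corpus, model, cfg = train_config(), quiet = TRUE) {
  if (length(corpus$train) == 0L) stop("empty train split")
  for (ty in corpus$entity_types)
    if (!any(grepl(paste0("-", ty, "$"), model$tag_dict$tags)))
      stop("model tag dictionary does not cover type ", ty)
  set.seed(cfg$seed)
  train <- corpus$train; dev <- corpus$dev
  Xtr <- embed_split(model$stack, train)
  Xdev <- embed_split(model$stack, dev)
  gold <- lapply(train, function(rec) gold_indices(model, rec))
  keep <- vapply(train, function(rec) n_tokens(rec$sentence) > 0L, FALSE)
  train <- train[keep]; Xtr <- Xtr[keep]; gold <- gold[keep]
  lr <- cfg$learning_rate
  best <- list(params = model$params, f1 = -Inf, epoch = 0L)
  bad_epochs <- 0L
  log <- data.frame(epoch = integer(0), lr = numeric(0),
                    train_loss = numeric(0), dev_f1 = numeric(0))
  audit <- unique(vapply(train, function(r) paste0(r$source, ":train"), ""))
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(seq_along(train))
    total <- 0
    bstart <- seq(1L, length(ord), by = cfg$batch_size)
    for (bs in bstart) {
      idx <- ord[bs:min(bs + cfg$batch_size - 1L, length(ord))]
      acc <- NULL
      for (i in idx) {
        sg <- sentence_grad(model, Xtr[[i]], gold[[i]])
        total <- total + sg$nll
        acc <- if (is.null(acc)) sg$grads else Map(`+`, acc, sg$grads)
      }
      acc <- lapply(acc, function(g) g / length(idx))
      model$params <- sgd_update(model$params, acc, lr, cfg$clip)
    }
    dev_f1 <- if (length(dev)) micro_f1_on(model, dev, Xdev) else NA_real_
    log <- rbind(log, data.frame(epoch = ep, lr = lr,
                                 train_loss = total / length(train),
                                 dev_f1 = dev_f1))
    if (!quiet)
      message(sprintf("epoch %d  lr %.4g  loss %.4f  dev F1 %.4f",
                      ep, lr, total / length(train), dev_f1))
    sel <- if (is.na(dev_f1)) -log$train_loss[ep] else dev_f1
    if (sel > best$f1 + 1e-12) {
      best <- list(params = model$params, f1 = sel, epoch = ep)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= cfg$patience) {
        lr <- lr * cfg$lr_decay_factor
        bad_epochs <- 0L
      }
    }
    if (lr < cfg$min_lr) break
  }
  model$params <- best$params
  attr(log, "best_dev_f1") <- if (length(dev)) best$f1 else NA_real_
  attr(log, "best_epoch") <- best$epoch
  attr(log, "audit") <- audit
  if (!is.null(cfg$checkpoint_dir)) write_run_dir(cfg, model, log)
  list(model = model, log = log)
}

write_run_dir <- function(cfg, model, log) {
  dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(cfg[setdiff(names(cfg), "checkpoint_dir")],
                       file.path(cfg$checkpoint_dir, "config.json"),
                       auto_unbox = TRUE)
  con <- file(file.path(cfg$checkpoint_dir, "epochs.jsonl"), "w")
  for (i in seq_len(nrow(log)))
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                na = "null"), con)
  close(con)
  save_tagger(model, file.path(cfg$checkpoint_dir, "best.ckpt"))
}

#' Train one model per entity type on the union of corpora
#'
#' Corpora in the pool that do not annotate `etype` are excluded with a
#' warning; the rest are merged with [merge_for_type()] and a fresh tagger
#' (tag dictionary containing only `etype` tags plus `O` and the reserved
#' states) is trained with [train_ner()].
#'
#' @param corpora list of [ner_corpus()].
#' @param etype entity type.
#' @param cfg a [train_config()].
#' @param stack an [embedding_stack()].
#' @param hidden_dim encoder size per direction.
#' @param ... passed to [tagger_model()].
#' @return `list(model, log, corpus)` (the merged corpus is returned so its
#'   per-corpus test splits can be evaluated).
#' @export
train_per_type <- function(corpora, etype, cfg, stack, hidden_dim = 32L, ...) {
  has <- vapply(corpora, function(co) etype %in% co$entity_types, FALSE)
  if (!any(has)) stop("no corpus annotates type ", etype)
  if (any(!has))
    warning("excluding corpora without type ", etype, ": ",
            paste(vapply(corpora[!has], function(co) co$name, ""),
                  collapse = ", "))
  merged <- merge_for_type(corpora[has], etype, seed = cfg$seed)
  dict <- tag_dictionary(tag_inventory(etype, "BIOES"))
  model <- tagger_model(stack, dict, hidden_dim = hidden_dim,
                        seed = cfg$seed, ...)
  fit <- train_ner(merged, model, cfg)
  list(model = fit$model, log = fit$log, corpus = merged)
}

#' Pretrain on a corpus pool, then finetune on a target corpus
#'
#' Phase 1 trains on the merged pool (which must not contain the target —
#' enforced by name as a leakage guard). Phase 2 continues from the phase-1
#' weights on the target's train and dev portions; because dev is consumed
#' for training, phase-2 model selection uses a seeded 10% holdout of the
#' target train split. Evaluation should only ever use the target's test
#' split.
#'
#' @param pool list of [ner_corpus()] (target already removed, see
#'   [remove_corpora()]).
#' @param target a [ner_corpus()].
#' @param etype entity type.
#' @param cfg_pre,cfg_ft [train_config()]s for the two phases.
#' @param stack an [embedding_stack()].
#' @param hidden_dim encoder size per direction.
#' @param holdout_fraction phase-2 selection holdout from target train.
#' @return `list(model, log_pre, log_ft, pretrained)`; `pretrained` is the
#'   phase-1 checkpoint. With an empty pool this reduces to plain training
#'   on the target.
#' @export
pretrain_finetune <- function(pool, target, etype, cfg_pre, cfg_ft, stack,
                              hidden_dim = 32L, holdout_fraction = 0.1) {
  if (target$name %in% vapply(pool, function(co) co$name, ""))
    stop("leakage guard: target corpus '", target$name, "' present in pool")
  dict <- tag_dictionary(tag_inventory(etype, "BIOES"))
  if (length(pool)) {
    pre <- train_per_type(pool, etype, cfg_pre, stack, hidden_dim)
    model <- pre$model; log_pre <- pre$log
  } else {
    model <- tagger_model(stack, dict, hidden_dim = hidden_dim,
                          seed = cfg_pre$seed)
    log_pre <- NULL
  }
  pretrained <- model
  tr <- filter_split_type(target$train, etype)
  dv <- filter_split_type(target$dev, etype)
  k <- max(1L, round(holdout_fraction * length(tr)))
  hold_idx <- local({ set.seed(cfg_ft$seed); sample(seq_along(tr), k) })
  ft_corpus <- ner_corpus(paste0(target$name, "-finetune"), etype,
                          train = c(tr[-hold_idx], dv),
                          dev = tr[hold_idx])
  fit <- train_ner(ft_corpus, model, cfg_ft)
  list(model = fit$model, log_pre = log_pre, log_ft = fit$log,
       pretrained = pretrained)
}
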
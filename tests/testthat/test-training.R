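small_corpus <- function(seed, n_train = 50L, n_dev = 15L, n_test = 20L,
                         name = "syn", ...) {
  generate_corpus(generator_spec(dictionaries = shared_gene_dict(),
                                 n_train = n_train, n_dev = n_dev,
                                 n_test = n_test, seed = seed, name = name,
                                 ...))
}

fast_cfg <- function(seed, epochs = 25L, lr = 2, patience = 4L)
  train_config(epochs = epochs, batch_size = 8L, learning_rate = lr,
               patience = patience, seed = seed)

test_that("train_config validates its fields", {
  expect_error(train_config(epochs = 0L), "epochs")
  expect_error(train_config(lr_decay_factor = 1), "lr_decay_factor")
  expect_error(train_config(patience = 0L), "patience")
  cfg <- train_config()
  expect_s3_class(cfg, "train_config")
})

test_that("train_ner overfits a small single-type corpus", {
  co <- small_corpus(61L)
  model <- tagger_model(toy_stack_small(),
                        tag_dictionary(tag_inventory("Gene", "BIOES")),
                        hidden_dim = 16L, seed = 61L)
  # capacity check: select on the train split itself, small batches,
  # constant learning rate (memorization run)
  co$dev <- co$train
  fit <- train_ner(co, model,
                   train_config(epochs = 60L, batch_size = 2L,
                                learning_rate = 2, patience = 99L,
                                seed = 61L))
  expect_equal(bioner:::micro_f1_on(fit$model, co$train), 1.0)
  # training log is well-formed and loss decreased
  expect_true(all(c("epoch", "lr", "train_loss", "dev_f1") %in%
                    names(fit$log)))
  expect_lt(tail(fit$log$train_loss, 1L), fit$log$train_loss[1L])
})

test_that("training is reproducible: same seed, same epoch logs", {
  co <- small_corpus(62L, n_train = 20L, n_dev = 5L)
  mk <- function() train_ner(
    co, tagger_model(toy_stack_small(),
                     tag_dictionary(tag_inventory("Gene", "BIOES")),
                     hidden_dim = 8L, seed = 62L),
    fast_cfg(62L, epochs = 5L))
  a <- mk(); b <- mk()
  expect_identical(a$log, b$log)
  expect_identical(a$model$params, b$model$params)
})

test_that("train_ner guards its preconditions", {
  co <- small_corpus(63L, n_train = 5L, n_dev = 2L)
  model <- tagger_model(toy_stack_small(),
                        tag_dictionary(tag_inventory("Gene", "BIOES")),
                        hidden_dim = 8L, seed = 63L)
  empty <- co; empty$train <- list()
  expect_error(train_ner(empty, model, fast_cfg(63L)), "empty train")
  wrong <- tagger_model(toy_stack_small(),
                        tag_dictionary(tag_inventory("Disease", "BIOES")),
                        hidden_dim = 8L, seed = 63L)
  expect_error(train_ner(co, wrong, fast_cfg(63L)), "does not cover")
})

test_that("best-dev checkpoint selection and leakage audit", {
  co <- small_corpus(64L, n_train = 30L, n_dev = 10L)
  model <- tagger_model(toy_stack_small(),
                        tag_dictionary(tag_inventory("Gene", "BIOES")),
                        hidden_dim = 8L, seed = 64L)
  fit <- train_ner(co, model, fast_cfg(64L, epochs = 10L))
  # recorded best equals the max over the epoch log
  expect_equal(attr(fit$log, "best_dev_f1"), max(fit$log$dev_f1))
  # returned model reproduces that dev F1
  expect_equal(bioner:::micro_f1_on(fit$model, co$dev),
               attr(fit$log, "best_dev_f1"))
  # leakage audit: only train-split sentences were presented to the optimizer
  audit <- attr(fit$log, "audit")
  expect_true(all(grepl(":train$", audit)))
  expect_false(any(grepl(":test$", audit)))
})

test_that("learning rate decays on dev plateau and training stops at min_lr", {
  co <- small_corpus(65L, n_train = 10L, n_dev = 5L)
  model <- tagger_model(toy_stack_small(),
                        tag_dictionary(tag_inventory("Gene", "BIOES")),
                        hidden_dim = 8L, seed = 65L)
  # learning rate 1e-8 cannot move the model: dev F1 plateaus immediately
  cfg <- train_config(epochs = 50L, learning_rate = 1e-8, patience = 2L,
                      lr_decay_factor = 0.5, min_lr = 0.3e-8, seed = 65L)
  fit <- train_ner(co, model, cfg)
  expect_lt(nrow(fit$log), 50L)           # stopped early
  expect_true(any(fit$log$lr < 1e-8))     # decay happened
})

test_that("training run directory holds config, epoch log, checkpoint", {
  dir <- withr::local_tempdir()
  co <- small_corpus(66L, n_train = 10L, n_dev = 4L)
  cfg <- fast_cfg(66L, epochs = 3L)
  cfg$checkpoint_dir <- dir
  model <- tagger_model(toy_stack_small(),
                        tag_dictionary(tag_inventory("Gene", "BIOES")),
                        hidden_dim = 8L, seed = 66L)
  fit <- train_ner(co, model, cfg)
  expect_true(file.exists(file.path(dir, "config.json")))
  lines <- readLines(file.path(dir, "epochs.jsonl"))
  expect_length(lines, nrow(fit$log))
  expect_equal(jsonlite::fromJSON(lines[1])$epoch, 1L)
  ck <- load_tagger(file.path(dir, "best.ckpt"))
  expect_identical(ck$params, fit$model$params)
})

test_that("train_per_type merges, filters and excludes non-annotating corpora", {
  a <- small_corpus(67L, n_train = 15L, n_dev = 5L, name = "a")
  b <- small_corpus(68L, n_train = 15L, n_dev = 5L, name = "b")
  dis <- generate_corpus(generator_spec("Disease", n_train = 5L, n_dev = 2L,
                                        n_test = 2L, seed = 69L,
                                        name = "dis"))
  expect_warning(
    fit <- train_per_type(list(a, b, dis), "Gene", fast_cfg(67L, epochs = 3L),
                          toy_stack_small(), hidden_dim = 8L),
    "excluding corpora")
  expect_length(fit$corpus$train, 30L)
  expect_named(fit$corpus$test_by_corpus, c("a", "b"))
  expect_equal(fit$model$tag_dict$tags,
               c("O", "B-Gene", "I-Gene", "E-Gene", "S-Gene"))
  expect_error(train_per_type(list(dis), "Gene", fast_cfg(67L),
                              toy_stack_small()), "no corpus annotates")
})

test_that("train_per_type on one corpus equals plain train_ner", {
  a <- small_corpus(70L, n_train = 12L, n_dev = 4L, name = "a")
  cfg <- fast_cfg(70L, epochs = 4L)
  via_pool <- train_per_type(list(a), "Gene", cfg, toy_stack_small(),
                             hidden_dim = 8L)
  merged <- merge_for_type(list(a), "Gene", seed = cfg$seed)
  direct <- train_ner(merged,
                      tagger_model(toy_stack_small(),
                                   tag_dictionary(tag_inventory("Gene",
                                                                "BIOES")),
                                   hidden_dim = 8L, seed = cfg$seed),
                      cfg)
  expect_identical(via_pool$model$params, direct$model$params)
})

test_that("merging convention-divergent corpora: mild divergence keeps
           in-corpus F1 close while improving cross-convention F1", {
  dicts <- shared_gene_dict()
  mk <- function(seed, long, name) generate_corpus(generator_spec(
    dictionaries = dicts, n_train = 80L, n_dev = 20L, n_test = 50L,
    keyword_rate = 0.15, include_trailing_keyword = long, seed = seed,
    name = name))
  A <- mk(71L, FALSE, "convA")
  B <- mk(72L, TRUE, "convB")
  cfg <- fast_cfg(71L, epochs = 20L)
  st <- toy_stack_small()
  fa <- train_per_type(list(A), "Gene", cfg, st, hidden_dim = 16L)
  fb <- train_per_type(list(B), "Gene", cfg, st, hidden_dim = 16L)
  fm <- train_per_type(list(A, B), "Gene", cfg, st, hidden_dim = 16L)
  proto <- match_protocol("exact_tolerant", 1L)
  f1 <- function(fit, recs) evaluate_model(fit$model, recs, proto)$micro$f1
  # within 10 pp of the single-corpus models on each component's test set
  expect_gte(f1(fm, A$test), f1(fa, A$test) - 0.10)
  expect_gte(f1(fm, B$test), f1(fb, B$test) - 0.10)
  # cross-convention F1 strictly above both single models' cross F1
  cross_m <- mean(c(f1(fm, A$test), f1(fm, B$test)))
  expect_gt(cross_m, f1(fa, B$test))
  expect_gt(cross_m, f1(fb, A$test))
})

test_that("pretrain_finetune guards leakage and restores phase-1 weights", {
  a <- small_corpus(73L, n_train = 10L, n_dev = 3L, name = "a")
  t <- small_corpus(74L, n_train = 10L, n_dev = 3L, name = "target")
  cfg <- fast_cfg(73L, epochs = 3L)
  expect_error(pretrain_finetune(list(a, t), t, "Gene", cfg, cfg,
                                 toy_stack_small(), hidden_dim = 8L),
               "leakage guard")
  out <- pretrain_finetune(list(a), t, "Gene", cfg, cfg, toy_stack_small(),
                           hidden_dim = 8L)
  # phase-1 checkpoint restorable bit-identically
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_tagger(out$pretrained, f)
  expect_identical(load_tagger(f)$params, out$pretrained$params)
  # with an empty pool the procedure reduces to plain training (no phase 1)
  vn <- pretrain_finetune(list(), t, "Gene", cfg, cfg, toy_stack_small(),
                          hidden_dim = 8L)
  expect_null(vn$log_pre)
  expect_s3_class(vn$model, "tagger_model")
})
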
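test_that("tag dictionary reserves START/STOP and rejects duplicates", {
  d <- tag_dictionary(tag_inventory("Gene", "BIOES"))
  expect_equal(d$tags[1], "O")
  expect_equal(d$K, 5L)
  expect_equal(c(d$start, d$stop), c(6L, 7L))
  expect_error(tag_dictionary(c("O", "O")), "duplicate")
  expect_error(bioner:::tag_index(d, "B-Disease"), "unknown tag")
})

test_that("score_path computes the additive chain score", {
  z1 <- matrix(0, 3L, 3L)
  expect_equal(score_path(matrix(0, 1, 1), z1, 1L), 0)
  e <- rbind(c(1, 0), c(0, 1))
  z2 <- matrix(0, 4L, 4L)
  expect_equal(score_path(e, z2, c(1L, 2L)), 2)
  # random instance: term-by-term oracle
  set.seed(1005)
  e <- matrix(rnorm(12), 4L, 3L)
  tr <- matrix(rnorm(25), 5L, 5L)
  p <- c(2L, 1L, 3L, 2L)
  manual <- tr[4, p[1]] + e[1, p[1]] + tr[p[1], p[2]] + e[2, p[2]] +
    tr[p[2], p[3]] + e[3, p[3]] + tr[p[3], p[4]] + e[4, p[4]] + tr[p[4], 5]
  expect_equal(score_path(e, tr, p), manual)
  expect_error(score_path(e, tr, c(1L, 2L, 3L)), "length")
  expect_error(score_path(e, tr, c(4L, 1L, 1L, 1L)), "out of range")
})

test_that("log_partition matches closed forms and rejects bad input", {
  expect_equal(log_partition(matrix(0, 1, 2), matrix(0, 4, 4)), log(2))
  expect_equal(log_partition(matrix(0, 1, 1), matrix(0, 3, 3)), 0)
  expect_error(log_partition(matrix(c(0, Inf), 1, 2), matrix(0, 4, 4)),
               "non-finite")
  expect_error(log_partition(matrix(0, 1, 2), matrix(0, 3, 3)), "START/STOP")
})

test_that("log_partition and viterbi agree with exhaustive enumeration", {
  set.seed(1006)
  for (rep in 1:40) {
    inst <- random_crf_instance()
    en <- enum_path_scores(inst$e, inst$trans)
    m <- max(en$scores)
    expect_equal(log_partition(inst$e, inst$trans),
                 m + log(sum(exp(en$scores - m))), tolerance = 1e-10)
    v <- viterbi(inst$e, inst$trans)
    expect_equal(v$score, max(en$scores))
    expect_equal(v$score, score_path(inst$e, inst$trans, v$path))
  }
})

test_that("nll_loss is a proper negative log-likelihood", {
  # single-tag inventory: only one path, loss 0
  e <- matrix(rnorm(3), 3L, 1L)
  tr <- matrix(rnorm(9), 3L, 3L)
  expect_equal(nll_loss(e, tr, c(1L, 1L, 1L)), 0)
  set.seed(1007)
  for (rep in 1:10) {
    inst <- random_crf_instance(max_T = 4L, max_K = 3L)
    en <- enum_path_scores(inst$e, inst$trans)
    gi <- sample(nrow(en$paths), 1L)
    gold <- unname(en$paths[gi, ])
    m <- max(en$scores)
    logZ <- m + log(sum(exp(en$scores - m)))
    gs <- en$scores[gi]
    expect_equal(nll_loss(inst$e, inst$trans, gold), -(gs - logZ),
                 tolerance = 1e-10)
    if (ncol(inst$e) > 1L)
      expect_gt(nll_loss(inst$e, inst$trans, gold), 0)
  }
})

test_that("path probabilities sum to one and are bounded by viterbi", {
  set.seed(1008)
  inst <- random_crf_instance(max_T = 5L, max_K = 4L)
  en <- enum_path_scores(inst$e, inst$trans)
  logZ <- log_partition(inst$e, inst$trans)
  expect_equal(sum(exp(en$scores - logZ)), 1, tolerance = 1e-8)
  expect_true(all(exp(en$scores - logZ) <= 1 + 1e-12))
  expect_true(all(viterbi(inst$e, inst$trans)$score >= en$scores))
})

test_that("viterbi tie-breaking is deterministic toward low indices", {
  e <- matrix(0, 3L, 4L)
  tr <- matrix(0, 6L, 6L)
  expect_equal(viterbi(e, tr)$path, c(1L, 1L, 1L))
  # decoupled chain: per-position argmax
  e2 <- rbind(c(0, 5, 0), c(7, 0, 0), c(0, 0, 2))
  expect_equal(viterbi(e2, matrix(0, 5, 5))$path, c(2L, 1L, 3L))
})

test_that("log_partition shifts by c under per-position emission shifts", {
  set.seed(1009)
  inst <- random_crf_instance(max_T = 5L, max_K = 4L)
  base <- log_partition(inst$e, inst$trans)
  for (cshift in c(-3, 0.5, 10)) {
    e2 <- inst$e
    pos <- sample(nrow(e2), 1L)
    e2[pos, ] <- e2[pos, ] + cshift
    expect_equal(log_partition(e2, inst$trans), base + cshift,
                 tolerance = 1e-10)
  }
})

test_that("CRF analytic gradients match finite differences", {
  set.seed(1010)
  e <- matrix(rnorm(8), 4L, 2L)
  tr <- matrix(rnorm(16), 4L, 4L)
  gold <- c(1L, 2L, 2L, 1L)
  fb <- bioner:::crf_grad(e, tr, gold)
  expect_equal(fb$nll, nll_loss(e, tr, gold))
  h <- 1e-6
  for (i in seq_len(nrow(e))) for (j in seq_len(ncol(e))) {
    ep <- e; em <- e
    ep[i, j] <- ep[i, j] + h; em[i, j] <- em[i, j] - h
    expect_equal(fb$d_e[i, j],
                 (nll_loss(ep, tr, gold) - nll_loss(em, tr, gold)) / (2 * h),
                 tolerance = 1e-5)
  }
  for (i in 1:4) for (j in 1:4) {
    tp <- tr; tm <- tr
    tp[i, j] <- tp[i, j] + h; tm[i, j] <- tm[i, j] - h
    expect_equal(fb$d_trans[i, j],
                 (nll_loss(e, tp, gold) - nll_loss(e, tm, gold)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("LSTM backward matches finite differences", {
  set.seed(1011)
  Tn <- 4L; D <- 3L; H <- 2L
  X <- matrix(rnorm(Tn * D), Tn, D)
  W <- matrix(rnorm(4 * H * D) * 0.4, 4 * H, D)
  U <- matrix(rnorm(4 * H * H) * 0.4, 4 * H, H)
  b <- rnorm(4 * H) * 0.2
  h0 <- rnorm(H) * 0.1; c0 <- rnorm(H) * 0.1
  R <- matrix(rnorm(Tn * H), Tn, H)   # random linear functional of H
  loss <- function(W., U., b., X.) {
    f <- bioner:::lstm_forward_cpp(X., W., U., b., h0, c0)
    sum(f$H * R)
  }
  fw <- bioner:::lstm_forward_cpp(X, W, U, b, h0, c0)
  bw <- bioner:::lstm_backward_cpp(X, W, U, h0, c0, fw$H, fw$C, fw$I, fw$F,
                                   fw$G, fw$O, fw$Tc, R, rep(0, H), rep(0, H))
  num <- function(par, f) {
    g <- par
    for (k in seq_along(par)) {
      p1 <- par; p1[k] <- p1[k] + 1e-6
      p2 <- par; p2[k] <- p2[k] - 1e-6
      g[k] <- (f(p1) - f(p2)) / 2e-6
    }
    g
  }
  expect_equal(bw$dW, num(W, function(p) loss(p, U, b, X)), tolerance = 1e-5)
  expect_equal(bw$dU, num(U, function(p) loss(W, p, b, X)), tolerance = 1e-5)
  expect_equal(as.numeric(bw$db), num(b, function(p) loss(W, U, p, X)),
               tolerance = 1e-5)
  expect_equal(bw$dX, num(X, function(p) loss(W, U, b, p)), tolerance = 1e-5)
})

test_that("predict produces well-formed mentions from any weights", {
  st <- toy_stack_small()
  model <- tagger_model(st, tag_dictionary(tag_inventory("Gene", "BIOES")),
                        hidden_dim = 8L, seed = 33L)
  s <- sent_words(c("ABC1", "binds", "XYZ2", "."))
  out <- predict_mentions(model, s)
  for (m in out) {
    expect_s3_class(m, "ner_mention")
    expect_identical(substr(s$text, m$start + 1L, m$end), m$text)
  }
  empty <- s; empty$tokens <- list()
  expect_length(predict_mentions(model, empty), 0L)
  # batch composition cannot change predictions (per-sentence processing)
  two <- predict(model, list(s, s))
  expect_identical(two[[1]], out)
  expect_identical(two[[2]], out)
})

test_that("a tagger overfits a single sentence to its gold mentions", {
  st <- toy_stack_small()
  s <- sent_words(c("KRAS7", "activates", "MAPK1", "signaling"))
  rec <- list(sentence = s, mentions = list(tok_mention(s, 1, 1, "Gene"),
                                            tok_mention(s, 3, 3, "Gene")))
  co <- ner_corpus("one", "Gene", train = list(rec), dev = list(rec))
  model <- tagger_model(st, tag_dictionary(tag_inventory("Gene", "BIOES")),
                        hidden_dim = 8L, seed = 34L)
  fit <- train_ner(co, model, train_config(epochs = 40L, batch_size = 1L,
                                           learning_rate = 2, patience = 10L,
                                           seed = 34L))
  got <- predict_mentions(fit$model, s)
  key <- function(x) sort(vapply(x, function(m)
    sprintf("%d:%d:%s", m$start, m$end, m$type), ""))
  expect_equal(key(got), key(rec$mentions))
})

test_that("strict transition mask forbids impossible BIOES bigrams", {
  dict <- tag_dictionary(tag_inventory("Gene", "BIOES"))
  st <- toy_stack_small()
  model <- tagger_model(st, dict, hidden_dim = 8L, mask_impossible = TRUE,
                        seed = 35L)
  expect_true(all(is.finite(model$params$trans + model$mask)))
  parse <- function(tag) c(substr(tag, 1, 1), substr(tag, 3, nchar(tag)))
  legal_pair <- function(a, b) {
    pa <- parse(a); pb <- parse(b)
    if (pa[1] %in% c("B", "I"))
      pb[1] %in% c("I", "E") && pb[2] == pa[2]
    else pb[1] %in% c("O", "B", "S")
  }
  set.seed(1012)
  for (rep in 1:20) {
    e <- matrix(rnorm(5 * dict$K, sd = 5), 5L, dict$K)
    path <- dict$tags[viterbi(e, bioner:::effective_trans(model))$path]
    for (t in seq_len(length(path) - 1L))
      expect_true(legal_pair(path[t], path[t + 1L]),
                  label = paste(path[t], "->", path[t + 1L]))
    expect_true(parse(path[1])[1] %in% c("O", "B", "S"))
    expect_true(parse(path[5])[1] %in% c("O", "E", "S"))
  }
})

test_that("tagger checkpoints round trip with version validation", {
  st <- toy_stack_small()
  model <- tagger_model(st, tag_dictionary(tag_inventory("Gene", "BIOES")),
                        hidden_dim = 8L, seed = 36L)
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_tagger(model, f)
  back <- load_tagger(f)
  expect_identical(back$params, model$params)
  s <- sent_words(c("ABC1", "binds"))
  expect_identical(predict_mentions(back, s), predict_mentions(model, s))
  saveRDS(list(format = "bioner_tagger", version = 2L), f)
  expect_error(load_tagger(f), "version-1 tagger")
})
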
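#' BiLSTM-CRF tagger model
#'
#' A frozen embedding stack feeds a bidirectional single-layer LSTM encoder
#' (hidden size `hidden_dim` per direction), a linear projection to per-tag
#' emission scores, and a linear-chain CRF transition matrix (with reserved
#' START/STOP states). Prediction runs embed, encode, emissions, Viterbi,
#' then span decoding; it is deterministic given the weights.
#'
#' By default transitions between structurally impossible BIOES bigrams
#' (e.g. `O -> E-X`) are learned rather than hard-masked; `mask_impossible =
#' TRUE` adds a large negative constant to them (kept finite so all
#' parameters stay finite).
#'
#' @param stack an [embedding_stack()] (frozen during NER training).
#' @param tag_dict a [tag_dictionary()].
#' @param hidden_dim encoder hidden size per direction.
#' @param scheme tag scheme used for span decoding.
#' @param mask_impossible apply the strict BIOES transition mask.
#' @param seed RNG seed for parameter initialization.
#' @return a `tagger_model`.
#' @export
tagger_model <- function(stack, tag_dict, hidden_dim = 32L,
                         scheme = c("BIOES", "IOB2"),
                         mask_impossible = FALSE, seed = 1L) {
  scheme <- match.arg(scheme)
  H <- as.integer(hidden_dim); D <- stack$total_dim; K <- tag_dict$K
  set.seed(seed)
  r <- function(nr, nc) matrix(runif(nr * nc, -0.1, 0.1), nr, nc)
  bgate <- rep(0, 4L * H); bgate[(H + 1L):(2L * H)] <- 1
  params <- list(Wf = r(4L * H, D), Uf = r(4L * H, H), bf = bgate,
                 Wb = r(4L * H, D), Ub = r(4L * H, H), bb = bgate,
                 Wout = r(2L * H, K), bout = rep(0, K),
                 trans = matrix(0, K + 2L, K + 2L))
  mask <- if (mask_impossible) bioes_transition_mask(tag_dict, scheme)
          else matrix(0, K + 2L, K + 2L)
  structure(list(stack = stack, tag_dict = tag_dict, hidden_dim = H,
                 scheme = scheme, params = params, mask = mask,
                 format_version = 1L),
            class = "tagger_model")
}

# additive mask: 0 where a transition is structurally possible, -1e4 elsewhere
bioes_transition_mask <- function(dict, scheme) {
  K <- dict$K; START <- dict$start; STOP <- dict$stop
  parse <- function(tag) if (tag == "O") list(prefix = "O", type = "")
           else list(prefix = substr(tag, 1, 1), type = substr(tag, 3, nchar(tag)))
  info <- lapply(dict$tags, parse)
  ok_from_outside <- function(p)
    if (scheme == "BIOES") p$prefix %in% c("O", "B", "S")
    else p$prefix %in% c("O", "B")
  closes <- function(p)
    if (scheme == "BIOES") p$prefix %in% c("O", "E", "S") else TRUE
  m <- matrix(-1e4, K + 2L, K + 2L)
  for (i in 1:K) for (j in 1:K) {
    a <- info[[i]]; b <- info[[j]]
    ok <- if (scheme == "BIOES") {
      if (a$prefix %in% c("B", "I"))
        b$prefix %in% c("I", "E") && b$type == a$type
      else ok_from_outside(b)
    } else {
      if (b$prefix == "I") a$prefix %in% c("B", "I") && a$type == b$type
      else TRUE
    }
    if (ok) m[i, j] <- 0
  }
  for (j in 1:K) if (ok_from_outside(info[[j]])) m[START, j] <- 0
  for (i in 1:K) if (closes(info[[i]])) m[i, STOP] <- 0
  m
}

effective_trans <- function(model) model$params$trans + model$mask

# encoder forward: returns emissions plus all caches needed for backprop
encode_forward <- function(model, X) {
  H <- model$hidden_dim
  z <- rep(0, H)
  fw <- lstm_forward_cpp(X, model$params$Wf, model$params$Uf, model$params$bf,
                         z, z)
  Xr <- X[rev(seq_len(nrow(X))), , drop = FALSE]
  bw <- lstm_forward_cpp(Xr, model$params$Wb, model$params$Ub, model$params$bb,
                         z, z)
  Hcat <- cbind(fw$H, bw$H[rev(seq_len(nrow(X))), , drop = FALSE])
  e <- Hcat %*% model$params$Wout +
    matrix(model$params$bout, nrow(X), model$tag_dict$K, byrow = TRUE)
  list(e = e, fw = fw, bw = bw, Hcat = Hcat, X = X, Xr = Xr)
}

# loss and parameter gradients for one sentence (embeddings frozen)
sentence_grad <- function(model, X, gold_idx) {
  enc <- encode_forward(model, X)
  H <- model$hidden_dim; Tn <- nrow(X)
  cg <- crf_grad(enc$e, effective_trans(model), gold_idx)
  dWout <- crossprod(enc$Hcat, cg$d_e)
  dbout <- colSums(cg$d_e)
  dHcat <- cg$d_e %*% t(model$params$Wout)
  z <- rep(0, H)
  gf <- lstm_backward_cpp(enc$X, model$params$Wf, model$params$Uf, z, z,
                          enc$fw$H, enc$fw$C, enc$fw$I, enc$fw$F, enc$fw$G,
                          enc$fw$O, enc$fw$Tc,
                          dHcat[, 1:H, drop = FALSE], z, z)
  dHb <- dHcat[, (H + 1L):(2L * H), drop = FALSE][rev(seq_len(Tn)), ,
                                                  drop = FALSE]
  gb <- lstm_backward_cpp(enc$Xr, model$params$Wb, model$params$Ub, z, z,
                          enc$bw$H, enc$bw$C, enc$bw$I, enc$bw$F, enc$bw$G,
                          enc$bw$O, enc$bw$Tc, dHb, z, z)
  list(nll = cg$nll,
       grads = list(Wf = gf$dW, Uf = gf$dU, bf = as.numeric(gf$db),
                    Wb = gb$dW, Ub = gb$dU, bb = as.numeric(gb$db),
                    Wout = dWout, bout = dbout, trans = cg$d_trans))
}

#' Predict entity mentions in a sentence
#'
#' @param model a [tagger_model()].
#' @param sent a [sentence()]; an empty sentence yields an empty list.
#' @param X optional precomputed embedding matrix for `sent` (cache).
#' @return list of [entity_mention()].
#' @export
predict_mentions <- function(model, sent, X = NULL) {
  if (n_tokens(sent) == 0L) return(list())
  if (is.null(X)) X <- embed_sentence(model$stack, sent)
  enc <- encode_forward(model, X)
  vit <- viterbi(enc$e, effective_trans(model))
  tags <- model$tag_dict$tags[vit$path]
  unclass_attr(tags_to_spans(sent, tags, model$scheme))
}

#' @export
predict.tagger_model <- function(object, newdata, ...) {
  if (inherits(newdata, "ner_sentence")) newdata <- list(newdata)
  lapply(newdata, function(s) predict_mentions(object, s))
}

#' @export
print.tagger_model <- function(x, ...) {
  cat(sprintf("<tagger_model tags=%d embed_dim=%d encoder=%d/dir scheme=%s>\n",
              x$tag_dict$K, x$stack$total_dim, x$hidden_dim, x$scheme))
  invisible(x)
}

#' Save / load a tagger checkpoint
#'
#' A versioned serialized archive holding the tag dictionary, embedding
#' stack configuration and all encoder/CRF parameters; loading validates the
#' format-version field.
#'
#' @param model a `tagger_model`.
#' @param path checkpoint path.
#' @export
save_tagger <- function(model, path) {
  saveRDS(list(format = "bioner_tagger", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_tagger
#' @export
load_tagger <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "bioner_tagger") || !identical(x$version, 1L))
    stop("not a version-1 tagger checkpoint: ", path)
  x$model
}
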
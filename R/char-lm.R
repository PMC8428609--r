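#' Character vocabulary
#'
#' Dense 1-based index over `UNK`, `BOS`, `EOS` plus the character inventory.
#' Characters unseen at training time always map to `UNK`; lookup never
#' fails.
#'
#' @param chars character vector (single characters, or strings that are
#'   split) forming the inventory.
#' @return a `char_vocab`.
#' @export
char_vocab <- function(chars) {
  inv <- unique(unlist(strsplit(chars, "", fixed = TRUE)))
  structure(list(chars = inv, size = length(inv) + 3L,
                 unk = 1L, bos = 2L, eos = 3L),
            class = "char_vocab")
}

char_ids <- function(vocab, text) {
  cs <- strsplit(text, "", fixed = TRUE)[[1L]]
  idx <- match(cs, vocab$chars)
  ifelse(is.na(idx), vocab$unk, idx + 3L)
}

#' Character-level recurrent language model
#'
#' A single-layer LSTM over characters with a softmax projection to the
#' vocabulary; trained by next-character cross-entropy. A `direction =
#' "backward"` model is trained on (and consumes) the reversed character
#' stream. The per-step output is a probability distribution over the vocab.
#'
#' @param vocab a [char_vocab()].
#' @param hidden_dim LSTM hidden size.
#' @param char_dim character embedding size.
#' @param direction `"forward"` or `"backward"`.
#' @param seed RNG seed for parameter initialization.
#' @return a `char_lm` (untrained; see [train_lm()]).
#' @export
char_lm <- function(vocab, hidden_dim = 32L, char_dim = 16L,
                    direction = c("forward", "backward"), seed = 1L) {
  direction <- match.arg(direction)
  V <- vocab$size; H <- as.integer(hidden_dim); D <- as.integer(char_dim)
  set.seed(seed)
  r <- function(nr, nc) matrix(runif(nr * nc, -0.1, 0.1), nr, nc)
  b <- rep(0, 4L * H)
  b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
  structure(list(vocab = vocab, direction = direction,
                 hidden_dim = H, char_dim = D,
                 params = list(E = r(V, D), W = r(4L * H, D),
                               U = r(4L * H, H), b = b,
                               P = r(H, V), q = rep(0, V)),
                 history = NULL, format_version = 1L),
            class = "char_lm")
}

# forward over an index sequence; returns hidden states (one row per input)
lm_hidden <- function(lm, ids, h0 = NULL, c0 = NULL) {
  H <- lm$hidden_dim
  if (is.null(h0)) h0 <- rep(0, H)
  if (is.null(c0)) c0 <- rep(0, H)
  X <- lm$params$E[ids, , drop = FALSE]
  lstm_forward_cpp(X, lm$params$W, lm$params$U, lm$params$b, h0, c0)
}

# log-softmax rows
log_softmax <- function(logits) {
  m <- apply(logits, 1L, max)
  sh <- logits - m
  sh - log(rowSums(exp(sh)))
}

# mean next-char negative log-likelihood of `text` under lm (direction-aware)
lm_mean_nll <- function(lm, text) {
  if (!nzchar(text)) stop("text must be non-empty")
  if (lm$direction == "backward") text <- str_rev(text)
  ids <- char_ids(lm$vocab, text)
  inputs <- c(lm$vocab$bos, ids[-length(ids)])
  fw <- lm_hidden(lm, inputs)
  logits <- fw$H %*% lm$params$P + matrix(lm$params$q, length(ids),
                                          lm$vocab$size, byrow = TRUE)
  lp <- log_softmax(logits)
  -mean(lp[cbind(seq_along(ids), ids)])
}

str_rev <- function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]),
                             collapse = "")

#' Perplexity of a character LM on text
#'
#' `exp` of the mean per-character negative log-likelihood; always `>= 1`,
#' and exactly `|vocab|` for a uniform model.
#'
#' @param lm a [char_lm()].
#' @param text non-empty string.
#' @return positive real.
#' @export
perplexity <- function(lm, text) exp(lm_mean_nll(lm, text))

#' Train a character-level language model
#'
#' Plain SGD on next-character cross-entropy with truncated backpropagation
#' through time: the stream is cut into `sequence_length` chunks and the
#' hidden state is carried (detached) between consecutive chunks; gradients
#' are averaged over `batch_size` consecutive chunks per update and clipped
#' to a global norm. Fully reproducible given `seed`.
#'
#' @param text training character stream (length `>=` `sequence_length`).
#' @param hidden_dim,char_dim model dimensions.
#' @param sequence_length TBPTT chunk length.
#' @param batch_size chunks per parameter update.
#' @param epochs passes over the stream.
#' @param learning_rate SGD step size.
#' @param clip global gradient-norm clip.
#' @param direction `"forward"` or `"backward"` (backward reverses the
#'   stream).
#' @param seed RNG seed (initialization).
#' @param vocab optional [char_vocab()]; default is built from `text`.
#' @return a trained `char_lm`; `$history` holds per-epoch training
#'   perplexity.
#' @export
train_lm <- function(text, hidden_dim = 32L, char_dim = 16L,
                     sequence_length = 50L, batch_size = 1L, epochs = 5L,
                     learning_rate = 0.5, clip = 5,
                     direction = c("forward", "backward"), seed = 1L,
                     vocab = NULL) {
  direction <- match.arg(direction)
  if (!nzchar(text)) stop("training text must be non-empty")
  if (nchar(text) < sequence_length)
    stop("text shorter than sequence_length")
  if (is.null(vocab)) vocab <- char_vocab(text)
  lm <- char_lm(vocab, hidden_dim, char_dim, direction, seed = seed)
  stream <- if (direction == "backward") str_rev(text) else text
  ids <- char_ids(vocab, stream)
  n <- length(ids)
  inputs <- c(vocab$bos, ids[-n])
  starts <- seq(1L, n, by = sequence_length)
  V <- vocab$size; H <- lm$hidden_dim
  hist <- data.frame(epoch = integer(0), train_ppl = numeric(0))
  for (ep in seq_len(epochs)) {
    h <- rep(0, H); c <- rep(0, H)
    acc <- NULL; acc_n <- 0L
    total_nll <- 0
    for (s in starts) {
      e <- min(s + sequence_length - 1L, n)
      idx_in <- inputs[s:e]; idx_out <- ids[s:e]
      Tn <- length(idx_in)
      X <- lm$params$E[idx_in, , drop = FALSE]
      fw <- lstm_forward_cpp(X, lm$params$W, lm$params$U, lm$params$b, h, c)
      logits <- fw$H %*% lm$params$P +
        matrix(lm$params$q, Tn, V, byrow = TRUE)
      lp <- log_softmax(logits)
      total_nll <- total_nll - sum(lp[cbind(seq_len(Tn), idx_out)])
      dlogits <- exp(lp)
      dlogits[cbind(seq_len(Tn), idx_out)] <-
        dlogits[cbind(seq_len(Tn), idx_out)] - 1
      dlogits <- dlogits / Tn
      dP <- crossprod(fw$H, dlogits)
      dq <- colSums(dlogits)
      dHm <- dlogits %*% t(lm$params$P)
      bw <- lstm_backward_cpp(X, lm$params$W, lm$params$U, h, c,
                              fw$H, fw$C, fw$I, fw$F, fw$G, fw$O, fw$Tc,
                              dHm, rep(0, H), rep(0, H))
      dE <- matrix(0, V, lm$char_dim)
      agg <- rowsum(bw$dX, group = idx_in)
      dE[as.integer(rownames(agg)), ] <- agg
      g <- list(E = dE, W = bw$dW, U = bw$dU, b = as.numeric(bw$db),
                P = dP, q = dq)
      acc <- if (is.null(acc)) g else Map(`+`, acc, g)
      acc_n <- acc_n + 1L
      if (acc_n >= batch_size || e == n) {
        acc <- lapply(acc, function(x) x / acc_n)
        lm$params <- sgd_update(lm$params, acc, learning_rate, clip)
        acc <- NULL; acc_n <- 0L
      }
      h <- as.numeric(fw$h_last); c <- as.numeric(fw$c_last)
    }
    hist <- rbind(hist, data.frame(epoch = ep,
                                   train_ppl = exp(total_nll / n)))
  }
  lm$history <- hist
  lm
}

# clipped plain-SGD step over a named list of parameter arrays
sgd_update <- function(params, grads, lr, clip) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  scale <- if (is.finite(clip) && gn > clip) clip / gn else 1
  for (nm in names(grads))
    params[[nm]] <- params[[nm]] - lr * scale * grads[[nm]]
  params
}

#' Contextual token embeddings from a forward/backward char-LM pair
#'
#' The sentence is processed as one character sequence (token texts joined
#' by single spaces). For each token, the forward half is the forward LM's
#' hidden state after consuming the token's *last* character; the backward
#' half is the backward LM's hidden state after consuming (in reverse) the
#' token's *first* character. Extraction is deterministic: no randomness is
#' touched.
#'
#' @param fwd,bwd trained (or initialized) [char_lm()] models of equal
#'   `hidden_dim` with directions forward and backward.
#' @param sent a [sentence()].
#' @return matrix `n_tokens x 2*hidden_dim`.
#' @export
embed_tokens <- function(fwd, bwd, sent) {
  if (fwd$hidden_dim != bwd$hidden_dim)
    stop("forward and backward LMs must share hidden_dim")
  if (fwd$direction != "forward" || bwd$direction != "backward")
    stop("embed_tokens needs a forward model and a backward model")
  nt <- n_tokens(sent)
  H <- fwd$hidden_dim
  if (nt == 0L) return(matrix(0, 0L, 2L * H))
  texts <- vapply(sent$tokens, function(t) t$text, "")
  joined <- paste(texts, collapse = " ")
  n <- nchar(joined)
  # 1-based char positions of each token within `joined`
  lens <- nchar(texts)
  firsts <- cumsum(c(1L, head(lens, -1L) + 1L))
  lasts <- firsts + lens - 1L
  fids <- c(fwd$vocab$bos, char_ids(fwd$vocab, joined))
  Hf <- lm_hidden(fwd, fids)$H
  bids <- c(bwd$vocab$bos, char_ids(bwd$vocab, str_rev(joined)))
  Hb <- lm_hidden(bwd, bids)$H
  out <- matrix(0, nt, 2L * H)
  for (i in seq_len(nt)) {
    out[i, 1:H] <- Hf[lasts[i] + 1L, ]            # after last char
    out[i, (H + 1L):(2L * H)] <- Hb[n - firsts[i] + 2L, ]  # rev pos of first
  }
  out
}

#' Save / load a character LM checkpoint
#'
#' The checkpoint is a versioned serialized archive (vocab, dims, direction,
#' parameters); loading validates the format-version field.
#'
#' @param lm a `char_lm`.
#' @param path checkpoint path.
#' @export
save_char_lm <- function(lm, path) {
  saveRDS(list(format = "bioner_char_lm", version = 1L, model = lm), path)
  invisible(path)
}

#' @rdname save_char_lm
#' @export
load_char_lm <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "bioner_char_lm") || !identical(x$version, 1L))
    stop("not a version-1 char LM checkpoint: ", path)
  x$model
}
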
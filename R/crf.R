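#' Tag dictionary with reserved START/STOP
#'
#' A bijection between tag strings and dense 1-based indices, plus reserved
#' `START` and `STOP` states used only by the CRF transition matrix (never
#' emitted for real tokens). Total size is `|tags| + 2`; `START = |tags|+1`,
#' `STOP = |tags|+2`.
#'
#' @param tags character vector of emittable tag strings (typically
#'   [tag_inventory()]).
#' @return a `tag_dictionary`.
#' @export
tag_dictionary <- function(tags) {
  if (anyDuplicated(tags)) stop("duplicate tags")
  K <- length(tags)
  structure(list(tags = tags, K = K, start = K + 1L, stop = K + 2L),
            class = "tag_dictionary")
}

tag_index <- function(dict, tags) {
  idx <- match(tags, dict$tags)
  if (anyNA(idx)) stop("unknown tag: '", tags[which(is.na(idx))[1L]], "'")
  idx
}

check_emissions <- function(e) {
  if (!is.matrix(e) || nrow(e) < 1L) stop("emissions must be a T x K matrix")
  if (any(!is.finite(e))) stop("non-finite emission score")
  invisible(e)
}

check_trans <- function(trans, K) {
  if (!is.matrix(trans) || nrow(trans) != K + 2L || ncol(trans) != K + 2L)
    stop("transition matrix must be (K+2) x (K+2) with START/STOP rows")
  invisible(trans)
}

#' Linear-chain CRF primitives
#'
#' Scores over tag sequences decompose additively:
#' `score = T[START, t1] + sum_i e[i, ti] + sum_i T[ti, t(i+1)] + T[tn, STOP]`
#' where `e` is the `n_tokens x K` emission matrix and `T` the
#' `(K+2) x (K+2)` transition matrix (row = from, column = to; `START` row
#' index `K+1`, `STOP` column index `K+2`).
#'
#' `log_partition()` computes `log sum_paths exp(score)` exactly with the
#' forward recursion in log space (max-shift log-sum-exp).
#' `nll_loss()` is `log_partition - score_path(gold)` and is non-negative.
#' `viterbi()` returns the maximizing path; ties are broken deterministically
#' toward the lowest tag index at the latest differing position, so an
#' all-zero score matrix decodes to the all-index-1 path.
#'
#' @param e emission matrix (`n_tokens x K`, finite).
#' @param trans transition matrix (`(K+2) x (K+2)`).
#' @param tags integer path (1-based tag indices, one per token).
#' @return `score_path()`/`log_partition()`: scalar; `nll_loss()`:
#'   non-negative scalar; `viterbi()`: `list(path, score)`.
#' @export
score_path <- function(e, trans, tags) {
  check_emissions(e)
  K <- ncol(e); Tn <- nrow(e)
  check_trans(trans, K)
  tags <- as.integer(tags)
  if (length(tags) != Tn) stop("path length must equal n_tokens")
  if (any(tags < 1L) || any(tags > K)) stop("tag index out of range")
  s <- trans[K + 1L, tags[1L]] + sum(e[cbind(seq_len(Tn), tags)]) +
    trans[tags[Tn], K + 2L]
  if (Tn > 1L) s <- s + sum(trans[cbind(tags[-Tn], tags[-1L])])
  s
}

lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

#' @rdname score_path
#' @export
log_partition <- function(e, trans) {
  check_emissions(e)
  K <- ncol(e); Tn <- nrow(e)
  check_trans(trans, K)
  a <- trans[K + 1L, 1:K] + e[1L, ]
  if (Tn > 1L) for (t in 2:Tn)
    a <- vapply(1:K, function(j) lse(a + trans[1:K, j]), 0) + e[t, ]
  lse(a + trans[1:K, K + 2L])
}

#' @rdname score_path
#' @param gold gold path (1-based tag indices).
#' @export
nll_loss <- function(e, trans, gold) {
  log_partition(e, trans) - score_path(e, trans, gold)
}

#' @rdname score_path
#' @export
viterbi <- function(e, trans) {
  check_emissions(e)
  K <- ncol(e); Tn <- nrow(e)
  check_trans(trans, K)
  delta <- trans[K + 1L, 1:K] + e[1L, ]
  bp <- matrix(0L, Tn, K)
  if (Tn > 1L) for (t in 2:Tn) {
    nd <- numeric(K)
    for (j in 1:K) {
      sc <- delta + trans[1:K, j]
      b <- which.max(sc)           # first max = lowest index
      bp[t, j] <- b
      nd[j] <- sc[b] + e[t, j]
    }
    delta <- nd
  }
  fin <- delta + trans[1:K, K + 2L]
  path <- integer(Tn)
  path[Tn] <- which.max(fin)
  if (Tn > 1L) for (t in Tn:2) path[t - 1L] <- bp[t, path[t]]
  list(path = path, score = fin[path[Tn]])
}

# forward-backward: returns nll plus exact gradients w.r.t. emissions and
# transitions (expected counts minus gold counts)
crf_grad <- function(e, trans, gold) {
  K <- ncol(e); Tn <- nrow(e)
  START <- K + 1L; STOP <- K + 2L
  alpha <- matrix(0, Tn, K)
  alpha[1L, ] <- trans[START, 1:K] + e[1L, ]
  if (Tn > 1L) for (t in 2:Tn)
    alpha[t, ] <- vapply(1:K, function(j) lse(alpha[t - 1L, ] + trans[1:K, j]),
                         0) + e[t, ]
  logZ <- lse(alpha[Tn, ] + trans[1:K, STOP])
  beta <- matrix(0, Tn, K)
  beta[Tn, ] <- trans[1:K, STOP]
  if (Tn > 1L) for (t in (Tn - 1L):1L)
    beta[t, ] <- vapply(1:K, function(i)
      lse(trans[i, 1:K] + e[t + 1L, ] + beta[t + 1L, ]), 0)
  marg <- exp(alpha + beta - logZ)           # unary marginals
  d_e <- marg
  d_e[cbind(seq_len(Tn), gold)] <- d_e[cbind(seq_len(Tn), gold)] - 1
  d_T <- matrix(0, K + 2L, K + 2L)
  d_T[START, 1:K] <- marg[1L, ]
  d_T[1:K, STOP] <- marg[Tn, ]
  if (Tn > 1L) for (t in 1:(Tn - 1L)) {
    pm <- exp(outer(alpha[t, ], e[t + 1L, ] + beta[t + 1L, ], `+`) +
                trans[1:K, 1:K] - logZ)
    d_T[1:K, 1:K] <- d_T[1:K, 1:K] + pm
  }
  d_T[START, gold[1L]] <- d_T[START, gold[1L]] - 1
  d_T[gold[Tn], STOP] <- d_T[gold[Tn], STOP] - 1
  if (Tn > 1L) for (t in 1:(Tn - 1L))
    d_T[gold[t], gold[t + 1L]] <- d_T[gold[t], gold[t + 1L]] - 1
  nll <- logZ - score_path(e, trans, gold)
  list(nll = nll, d_e = d_e, d_trans = d_T, logZ = logZ)
}
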
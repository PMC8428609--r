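#' Span-matching protocols
#'
#' Two mention-level protocols: `exact_tolerant` requires type equality and
#' each boundary independently within `tolerance` characters of gold
#' (`tolerance = 1` absorbs differences in the handling of special
#' characters; `tolerance = 0` is strict span equality); `overlap` counts any
#' same-type span intersection as a match and ignores the tolerance.
#'
#' With `whole_span_shift = TRUE` the tolerant protocol instead requires both
#' boundaries to be shifted by the *same* offset within the tolerance (a
#' strictly stricter reading; the per-boundary default subsumes it).
#'
#' @param mode `"exact_tolerant"` or `"overlap"`.
#' @param tolerance non-negative integer character tolerance.
#' @param whole_span_shift see above.
#' @return a `match_protocol`.
#' @export
match_protocol <- function(mode = c("exact_tolerant", "overlap"),
                           tolerance = 1L, whole_span_shift = FALSE) {
  mode <- match.arg(mode)
  tolerance <- as.integer(tolerance)
  if (tolerance < 0L) stop("tolerance must be >= 0")
  structure(list(mode = mode, tolerance = tolerance,
                 whole_span_shift = whole_span_shift),
            class = "match_protocol")
}

#' @rdname match_protocol
#' @param gold,pred [entity_mention()]s.
#' @param protocol a `match_protocol`.
#' @return `is_match()`: logical scalar.
#' @export
is_match <- function(gold, pred, protocol) {
  if (gold$type != pred$type) return(FALSE)
  if (protocol$mode == "overlap")
    return(max(gold$start, pred$start) < min(gold$end, pred$end))
  ds <- pred$start - gold$start; de <- pred$end - gold$end
  if (protocol$whole_span_shift)
    ds == de && abs(ds) <= protocol$tolerance
  else
    abs(ds) <= protocol$tolerance && abs(de) <= protocol$tolerance
}

#' Match gold and predicted mentions, count TP/FP/FN per type
#'
#' One-to-one greedy matching: within each type, candidate pairs are visited
#' in `(gold.start, pred.start)` order and each gold and each predicted
#' mention is consumed at most once. Unmatched predictions are false
#' positives; unmatched golds are false negatives. With `maximum = TRUE` an
#' exhaustive maximum bipartite matching is used instead (sensitivity
#' check; only feasible for small lists).
#'
#' @param gold,pred lists of [entity_mention()] from the same document scope.
#' @param protocol a [match_protocol()].
#' @param maximum use maximum instead of greedy matching.
#' @return data.frame with columns `type, tp, fp, fn` (one row per type seen
#'   in either list).
#' @export
match_and_count <- function(gold, pred, protocol, maximum = FALSE) {
  types <- unique(c(vapply(gold, function(m) m$type, ""),
                    vapply(pred, function(m) m$type, "")))
  rows <- lapply(types, function(ty) {
    g <- Filter(function(m) m$type == ty, gold)
    p <- Filter(function(m) m$type == ty, pred)
    tp <- if (maximum) max_matching_size(g, p, protocol)
          else greedy_matching_size(g, p, protocol)
    data.frame(type = ty, tp = tp, fp = length(p) - tp, fn = length(g) - tp)
  })
  if (length(rows) == 0L)
    return(data.frame(type = character(0), tp = integer(0), fp = integer(0),
                      fn = integer(0)))
  do.call(rbind, rows)
}

greedy_matching_size <- function(g, p, protocol) {
  if (length(g) == 0L || length(p) == 0L) return(0L)
  ord_g <- order(vapply(g, function(m) m$start, 0L))
  ord_p <- order(vapply(p, function(m) m$start, 0L))
  used_p <- rep(FALSE, length(p))
  tp <- 0L
  for (i in ord_g) for (j in ord_p) {
    if (used_p[j]) next
    if (is_match(g[[i]], p[[j]], protocol)) {
      used_p[j] <- TRUE; tp <- tp + 1L
      break
    }
  }
  tp
}

# exhaustive augmenting-path maximum bipartite matching (small lists only)
max_matching_size <- function(g, p, protocol) {
  ng <- length(g); np <- length(p)
  if (ng == 0L || np == 0L) return(0L)
  adj <- lapply(seq_len(ng), function(i)
    which(vapply(seq_len(np), function(j) is_match(g[[i]], p[[j]], protocol),
                 FALSE)))
  match_p <- rep(0L, np)
  try_aug <- function(i, seen) {
    for (j in adj[[i]]) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (match_p[j] == 0L || Recall(match_p[j], seen)) {
        match_p[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  tp <- 0L
  for (i in seq_len(ng)) if (try_aug(i, rep(FALSE, np))) tp <- tp + 1L
  tp
}

#' Precision/recall/F1 report from per-type counts
#'
#' Precision is `tp/(tp+fp)`, recall `tp/(tp+fn)`, F1 `2PR/(P+R)`, each 0
#' when its denominator is 0. The micro aggregate pools counts across types;
#' the macro aggregate is the unweighted mean of per-type F1. Values are
#' kept as proportions in `[0,1]`; `print()` renders percentages rounded to
#' two decimals.
#'
#' @param counts data.frame `type, tp, fp, fn` (rows with the same type are
#'   pooled).
#' @return an `eval_report`: list with `$per_type` (data.frame adding
#'   precision/recall/f1), `$micro`, `$macro_f1`.
#' @export
eval_report <- function(counts) {
  if (nrow(counts)) {
    counts <- stats::aggregate(cbind(tp, fp, fn) ~ type, counts, sum)
    counts <- counts[order(counts$type), , drop = FALSE]
  }
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(precision = p, recall = r, f1 = f)
  }
  per <- counts
  if (nrow(per)) {
    m <- t(mapply(function(tp, fp, fn) prf(tp, fp, fn),
                  per$tp, per$fp, per$fn))
    per <- cbind(per, as.data.frame(m))
  } else {
    per <- cbind(per, data.frame(precision = numeric(0), recall = numeric(0),
                                 f1 = numeric(0)))
  }
  micro <- prf(sum(counts$tp), sum(counts$fp), sum(counts$fn))
  macro <- if (nrow(per)) mean(per$f1) else 0
  structure(list(per_type = per,
                 micro = as.list(micro),
                 macro_f1 = macro),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  pct <- function(v) sprintf("%.2f", 100 * v)
  cat("mention-level evaluation\n")
  if (nrow(x$per_type))
    for (i in seq_len(nrow(x$per_type))) {
      r <- x$per_type[i, ]
      cat(sprintf("  %-10s tp=%4d fp=%4d fn=%4d  P=%6s R=%6s F1=%6s\n",
                  r$type, r$tp, r$fp, r$fn, pct(r$precision), pct(r$recall),
                  pct(r$f1)))
    }
  cat(sprintf("  micro: P=%s R=%s F1=%s   macro-F1=%s\n",
              pct(x$micro$precision), pct(x$micro$recall), pct(x$micro$f1),
              pct(x$macro_f1)))
  invisible(x)
}

#' Evaluate predictions against gold over a corpus split
#'
#' Counts are pooled per sentence (matching never crosses sentences), then
#' aggregated into an [eval_report()].
#'
#' @param records list of `list(sentence, mentions)` gold records.
#' @param predictions list (parallel to `records`) of predicted mention
#'   lists.
#' @param protocol a [match_protocol()].
#' @export
evaluate_predictions <- function(records, predictions,
                                 protocol = match_protocol()) {
  if (length(records) != length(predictions))
    stop("records and predictions must be parallel lists")
  counts <- do.call(rbind, c(
    list(data.frame(type = character(0), tp = integer(0), fp = integer(0),
                    fn = integer(0))),
    lapply(seq_along(records), function(i)
      match_and_count(records[[i]]$mentions, predictions[[i]], protocol))))
  eval_report(counts)
}

#' @rdname evaluate_predictions
#' @param model a [tagger_model()].
#' @export
evaluate_model <- function(model, records, protocol = match_protocol()) {
  preds <- lapply(records, function(r) predict_mentions(model, r$sentence))
  evaluate_predictions(records, preds, protocol)
}
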
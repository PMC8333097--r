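#' Classify one sound item by frame-posterior voting
#'
#' Frames are tiled over the item at stride `cw_shift`, the per-frame
#' log-posteriors are exponentiated and averaged, and the class maximizing
#' the mean posterior wins (lowest index on ties). Uncut items shorter than
#' one frame are completed with surrounding audio, the call centred
#' (deterministically) in the window.
#'
#' @param model A trained [sincbird_model].
#' @param item One element of [load_items()].
#' @param cw_shift_ms Evaluation stride in ms (default: the model's
#'   configured shift).
#' @param log_space Average log-posteriors instead of posteriors (off by
#'   default: voting uses the average posterior).
#' @param max_batch Frames per forward pass.
#' @return List with `pred` (0-based class), `posterior` (mean posterior
#'   vector) and `n_frames`.
#' @export
classify_file <- function(model, item, cw_shift_ms = NULL, log_space = FALSE,
                          max_batch = 512L) {
  w <- model$frame_len
  shift <- max(1L, frame_samples(cw_shift_ms %||% model$cfg$cw_shift,
                                 model$cfg$fs))
  x <- item$samples
  if (identical(item$dialect, "uncut")) {
    i0 <- item$call_start; len <- item$call_len
    if (len < w) {
      # deterministic completion: centre the call in one frame
      lo <- max(0L, min(i0 + len - w, i0 - (w - len) %/% 2L))
      lo <- min(lo, length(x) - w)
      if (lo < 0) stop("recording too short for one frame")
      x <- x[(lo + 1):(lo + w)]
    } else {
      x <- x[(i0 + 1):(i0 + len)]
    }
  }
  nf <- n_frames(length(x), w, shift)
  if (nf < 1) stop("item yields zero frames (", length(x), " samples < ", w, ")")
  starts <- (seq_len(nf) - 1L) * shift
  post <- numeric(model$cfg$n_classes)
  done <- 0L
  while (done < nf) {
    take <- min(max_batch, nf - done)
    X <- matrix(0, take, w)
    for (r in seq_len(take)) {
      s0 <- starts[done + r]
      X[r, ] <- x[(s0 + 1):(s0 + w)]
    }
    logp <- forward(model, X, training = FALSE)
    post <- post + if (log_space) colSums(logp) else colSums(exp(logp))
    done <- done + take
  }
  post <- post / nf
  if (log_space) post <- exp(post - max(post)) / sum(exp(post - max(post)))
  list(pred = which.max(post) - 1L, posterior = post, n_frames = nf)
}

#' Classify a list of items and collect metrics
#'
#' @param model A trained [sincbird_model].
#' @param items Item list from [load_items()].
#' @param cw_shift_ms Evaluation stride in ms.
#' @return An `eval_report` from [compute_metrics()] plus the per-item
#'   posterior matrix.
#' @export
evaluate_items <- function(model, items, cw_shift_ms = NULL) {
  n <- length(items)
  truth <- vapply(items, function(x) x$class_index, 0L)
  preds <- integer(n)
  post <- matrix(0, n, model$cfg$n_classes)
  for (i in seq_len(n)) {
    r <- classify_file(model, items[[i]], cw_shift_ms)
    preds[i] <- r$pred
    post[i, ] <- r$posterior
  }
  compute_metrics(truth, preds, post)
}

#' Support-weighted one-vs-rest ROC AUC
#'
#' Each class present in the truth is scored against the rest using its
#' mean-posterior column; the per-class AUC is the midrank (Mann-Whitney)
#' statistic, combined by support weighting. Classes absent from the truth
#' are excluded with a warning.
#'
#' @param truth Integer 0-based true classes.
#' @param posteriors Matrix `(n, n_classes)` of scores.
#' @return Weighted AUC in `[0, 1]`.
#' @export
roc_auc_ovr <- function(truth, posteriors) {
  n_classes <- ncol(posteriors)
  present <- sort(unique(truth))
  absent <- setdiff(seq_len(n_classes) - 1L, present)
  if (length(absent)) {
    warning("class(es) absent from test truth excluded from AUC: ",
            paste(absent, collapse = ", "))
  }
  aucs <- numeric(0)
  wts <- numeric(0)
  for (c0 in present) {
    pos <- truth == c0
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) next
    r <- rank(posteriors[, c0 + 1L]) # midranks handle ties
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    aucs <- c(aucs, auc)
    wts <- c(wts, n1)
  }
  sum(aucs * wts) / sum(wts)
}

#' Top-k accuracy
#'
#' Fraction of items whose true class ranks among the `k` largest scores
#' (lowest class index wins ties, matching the argmax tie-break).
#'
#' @param truth Integer 0-based true classes.
#' @param posteriors Score matrix.
#' @param k Rank cut-off.
#' @return Fraction in `[0, 1]`.
#' @export
topk_accuracy <- function(truth, posteriors, k) {
  k <- min(k, ncol(posteriors))
  hits <- vapply(seq_along(truth), function(i) {
    ord <- order(posteriors[i, ], decreasing = TRUE)
    (truth[i] + 1L) %in% ord[seq_len(k)]
  }, TRUE)
  mean(hits)
}

#' Row-proportion confusion matrix
#'
#' Row `r` is the distribution of predicted classes among items whose true
#' class is `r`; rows of classes unobserved in the truth are all zero and
#' flagged in the `"observed"` attribute. Accuracy equals the
#' support-weighted mean of the diagonal.
#'
#' @param truth,pred Integer 0-based classes.
#' @param n_classes Total class count.
#' @param class_names Optional dimnames.
#' @return `n_classes x n_classes` matrix with attribute `observed`.
#' @export
confusion_proportions <- function(truth, pred, n_classes, class_names = NULL) {
  m <- matrix(0, n_classes, n_classes)
  for (i in seq_along(truth)) {
    m[truth[i] + 1L, pred[i] + 1L] <- m[truth[i] + 1L, pred[i] + 1L] + 1
  }
  rs <- rowSums(m)
  observed <- rs > 0
  m[observed, ] <- m[observed, , drop = FALSE] / rs[observed]
  if (!is.null(class_names)) dimnames(m) <- list(true = class_names,
                                                 predicted = class_names)
  attr(m, "observed") <- observed
  m
}

#' Full metric suite for file-level predictions
#'
#' Accuracy, support-weighted one-vs-rest ROC AUC computed from the mean
#' posteriors, support-weighted precision/recall/F1, top-3 and top-5
#' accuracy, and the row-proportion confusion matrix.
#'
#' @param truth Integer 0-based true classes.
#' @param pred Integer 0-based predicted classes.
#' @param posteriors Matrix `(n, n_classes)` of mean posteriors
#'   (row-stochastic).
#' @param class_names Optional class labels for the confusion matrix.
#' @return Object of class `eval_report`: list with `per_file`
#'   (data.frame `truth`, `pred`, `correct`), `posteriors`, `confusion`,
#'   and scalar metrics `accuracy`, `roc_auc`, `precision`, `recall`, `f1`,
#'   `top3`, `top5`.
#' @export
compute_metrics <- function(truth, pred, posteriors, class_names = NULL) {
  stopifnot(length(truth) >= 1, length(truth) == length(pred),
            nrow(posteriors) == length(truth))
  n_classes <- ncol(posteriors)
  acc <- mean(truth == pred)

  # support-weighted precision / recall / F1 (absent denominator -> 0)
  prec <- rec <- f1 <- numeric(0)
  wts <- numeric(0)
  for (c0 in sort(unique(truth))) {
    tp <- sum(pred == c0 & truth == c0)
    fp <- sum(pred == c0 & truth != c0)
    fn <- sum(pred != c0 & truth == c0)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    prec <- c(prec, p); rec <- c(rec, r); f1 <- c(f1, f)
    wts <- c(wts, sum(truth == c0))
  }
  w <- wts / sum(wts)

  structure(
    list(
      per_file = data.frame(truth = truth, pred = pred,
                            correct = truth == pred),
      posteriors = posteriors,
      confusion = confusion_proportions(truth, pred, n_classes, class_names),
      accuracy = acc,
      roc_auc = roc_auc_ovr(truth, posteriors),
      precision = sum(prec * w),
      recall = sum(rec * w),
      f1 = sum(f1 * w),
      top3 = topk_accuracy(truth, posteriors, 3),
      top5 = topk_accuracy(truth, posteriors, 5)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("File-level evaluation over", nrow(x$per_file), "items\n")
  for (m in c("accuracy", "roc_auc", "precision", "recall", "f1",
              "top3", "top5")) {
    cat(sprintf("  %-9s %.4f\n", m, x[[m]]))
  }
  invisible(x)
}

#' Overlap credit analysis
#'
#' Field recordings often contain simultaneous vocalizations of several
#' species; a prediction landing on a species overlapping the tagged call
#' is arguably not a full error. This recomputes accuracy crediting a
#' prediction that matches the event tag OR any tag overlapping the event's
#' interval, and summarizes where predictions land for events that have
#' overlaps.
#'
#' @param truth_tags Character vector of event tags.
#' @param pred_tags Character vector of predicted tags.
#' @param overlap_sets List of character vectors: other tags overlapping
#'   each event (see [overlapping_tags()]).
#' @return List with `strict_accuracy`, `credited_accuracy`,
#'   `credit_gain` (credited - strict), `errors_on_overlap` (fraction of
#'   wrong predictions landing on an overlapping tag),
#'   `on_tag_or_overlap` (fraction of predictions on the tag or an overlap,
#'   among events that have overlaps), and `split` (share of those
#'   predictions on the tag vs. on an overlap).
#' @export
overlap_credit <- function(truth_tags, pred_tags, overlap_sets) {
  n <- length(truth_tags)
  stopifnot(length(pred_tags) == n, length(overlap_sets) == n)
  on_tag <- pred_tags == truth_tags
  on_ovl <- vapply(seq_len(n), function(i) pred_tags[i] %in% overlap_sets[[i]], TRUE)
  strict <- mean(on_tag)
  credited <- mean(on_tag | on_ovl)
  has_ovl <- vapply(overlap_sets, length, 0L) > 0
  hit <- on_tag | on_ovl
  on_rate <- if (any(has_ovl)) mean(hit[has_ovl]) else NA_real_
  n_hit <- sum(hit[has_ovl])
  split <- if (any(has_ovl) && n_hit > 0) {
    c(tagged = sum(on_tag[has_ovl] & hit[has_ovl]) / n_hit,
      overlap = sum(!on_tag[has_ovl] & hit[has_ovl]) / n_hit)
  } else {
    c(tagged = NA_real_, overlap = NA_real_)
  }
  wrong <- !on_tag
  list(
    strict_accuracy = strict,
    credited_accuracy = credited,
    credit_gain = credited - strict,
    errors_on_overlap = if (any(wrong)) mean(on_ovl[wrong]) else NA_real_,
    on_tag_or_overlap = on_rate,
    split = split
  )
}
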
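#' Training hyperparameters
#'
#' Defaults follow the study setup: RMSprop at learning rate 0.001 with
#' minibatches of 128 frames, training for 200 epochs. An epoch is defined
#' as `batches_per_epoch` minibatches (hardware-independent). Random
#' amplification multiplies each sampled frame by a gain drawn uniformly
#' from `1 +/- amp_factor`; 0 disables it.
#'
#' @param learning_rate RMSprop learning rate.
#' @param batch_size Frames per minibatch.
#' @param n_epochs Training epochs.
#' @param batches_per_epoch Minibatches per epoch.
#' @param amp_factor Random-amplification half-range in `[0, 1)`.
#' @param eval_every Epochs between test-set evaluations (file-level
#'   accuracy recorded in the history); `Inf` disables mid-training
#'   evaluation.
#' @param rmsprop_alpha Smoothing constant of the squared-gradient average.
#' @param eps RMSprop denominator floor.
#' @param seed Master seed; window-sampling and amplification use separate
#'   streams derived from it.
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 128,
                         n_epochs = 200, batches_per_epoch = 800,
                         amp_factor = 0.2, eval_every = 10,
                         rmsprop_alpha = 0.95, eps = 1e-8, seed = 1) {
  stopifnot(learning_rate >= 0, batch_size >= 1, amp_factor >= 0, amp_factor < 1)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         n_epochs = as.integer(n_epochs),
         batches_per_epoch = as.integer(batches_per_epoch),
         amp_factor = amp_factor, eval_every = eval_every,
         rmsprop_alpha = rmsprop_alpha, eps = eps, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Load the audio behind a file list into memory
#'
#' Cut dialect: each row's segment WAV is read whole. Uncut dialect: the
#' original recording is read (cached per path) and the event's position is
#' kept so frames can be completed with surrounding audio.
#'
#' @param lst data.frame from [build_file_lists()] (`train` or `test`).
#' @param dialect `"cut"` or `"uncut"`.
#' @return List of items; each has `samples`, `class_index`, `tag`, and for
#'   the uncut dialect `call_start`/`call_len` (sample offsets of the
#'   labeled call inside `samples`).
#' @export
load_items <- function(lst, dialect = c("cut", "uncut")) {
  dialect <- match.arg(dialect)
  items <- vector("list", nrow(lst))
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(lst))) {
    if (dialect == "cut") {
      w <- read_wav(lst$path[i])
      items[[i]] <- list(samples = w$samples, fs = w$fs,
                         class_index = lst$class_index[i], tag = lst$tag[i],
                         dialect = "cut")
    } else {
      key <- lst$path[i]
      if (is.null(cache[[key]])) cache[[key]] <- read_wav(key)
      w <- cache[[key]]
      i0 <- as.integer(round(lst$start[i] * w$fs))
      len <- as.integer(round(lst$duration[i] * w$fs))
      items[[i]] <- list(samples = w$samples, fs = w$fs,
                         class_index = lst$class_index[i], tag = lst$tag[i],
                         call_start = i0, call_len = len, dialect = "uncut")
    }
  }
  items
}

#' Extract one training frame from an item
#'
#' Cut dialect: the window start is uniform over the valid positions inside
#' the segment. Uncut dialect: uniform inside the labeled call; when the
#' call is shorter than the frame, surrounding audio of the original file
#' completes the window and the call sits uniformly at random inside it,
#' wholly contained.
#'
#' @param item One element of [load_items()].
#' @param frame_len Frame length in samples.
#' @param rng An [rng_stream] for the window position.
#' @return Numeric vector of `frame_len` samples.
#' @export
extract_frame <- function(item, frame_len, rng) {
  if (item$dialect == "cut") {
    n <- length(item$samples)
    if (n < frame_len) {
      stop("segment of ", n, " samples shorter than frame (", frame_len,
           "); should have been excluded upstream")
    }
    s0 <- if (n == frame_len) 0L else rng$sample_int(n - frame_len + 1L, 1L) - 1L
    item$samples[(s0 + 1):(s0 + frame_len)]
  } else {
    n <- length(item$samples)
    i0 <- item$call_start
    len <- item$call_len
    if (len >= frame_len) {
      s0 <- i0 + rng$sample_int(len - frame_len + 1L, 1L) - 1L
    } else {
      # window must contain the whole call: start in [i0 + len - frame, i0]
      lo <- max(0L, i0 + len - frame_len)
      hi <- min(n - frame_len, i0)
      if (hi < lo) stop("recording too short to complete the frame")
      s0 <- lo + rng$sample_int(hi - lo + 1L, 1L) - 1L
    }
    item$samples[(s0 + 1):(s0 + frame_len)]
  }
}

#' Random amplification augmentation
#'
#' Multiplies the frame by a single gain `a ~ Uniform(1 - amp_factor,
#' 1 + amp_factor)`; `amp_factor = 0` is the identity.
#'
#' @param frame Numeric frame.
#' @param amp_factor Half-range in `[0, 1)`.
#' @param rng An [rng_stream] dedicated to amplification.
#' @return Scaled frame.
#' @export
random_amplify <- function(frame, amp_factor, rng) {
  if (amp_factor == 0) return(frame)
  frame * rng$runif(1, 1 - amp_factor, 1 + amp_factor)
}

# one RMSprop step over every layer parameter
rmsprop_step <- function(model, lr, alpha, eps) {
  for (l in model$layers) {
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      c0 <- l$opt[[nm]]
      if (is.null(c0)) c0 <- g * 0
      c1 <- alpha * c0 + (1 - alpha) * g * g
      l$opt[[nm]] <- c1
      l$params[[nm]] <- l$params[[nm]] - lr * g / (sqrt(c1) + eps)
    }
  }
}

# mean negative log-likelihood of true classes under log-posteriors
nll_loss <- function(logp, classes0) {
  idx <- cbind(seq_len(nrow(logp)), classes0 + 1L)
  -mean(logp[idx])
}

#' Train a frame classifier
#'
#' Each minibatch draws `batch_size` frames from uniformly random training
#' items (a frame inherits its item's class), applies random amplification,
#' and takes one RMSprop step on the frame-level negative log-likelihood.
#' The history records per-epoch mean training loss and, every `eval_every`
#' epochs, file-level test accuracy via [classify_file()] voting. Fully
#' reproducible given the config seeds.
#'
#' @param model A [build_model()] result (modified in place and returned).
#' @param train_items,test_items Item lists from [load_items()].
#' @param tcfg A [train_config].
#' @param verbose Print one line per epoch.
#' @return List with `model` and `history` (data.frame `epoch`, `loss`,
#'   `test_accuracy`).
#' @export
train <- function(model, train_items, test_items = NULL, tcfg = train_config(),
                  verbose = FALSE) {
  if (length(train_items) == 0) stop("empty training split")
  classes <- vapply(train_items, function(x) x$class_index, 0L)
  if (length(unique(classes)) < 2) stop("training split must contain >= 2 classes")
  frame_len <- model$frame_len
  win_rng <- rng_stream(derive_seed(tcfg$seed, 11))
  amp_rng <- rng_stream(derive_seed(tcfg$seed, 12))

  history <- data.frame(epoch = integer(), loss = numeric(),
                        test_accuracy = numeric())
  n_items <- length(train_items)
  for (epoch in seq_len(tcfg$n_epochs)) {
    losses <- numeric(tcfg$batches_per_epoch)
    for (b in seq_len(tcfg$batches_per_epoch)) {
      ids <- win_rng$sample_int(n_items, tcfg$batch_size, replace = TRUE)
      X <- matrix(0, tcfg$batch_size, frame_len)
      for (r in seq_len(tcfg$batch_size)) {
        fr <- extract_frame(train_items[[ids[r]]], frame_len, win_rng)
        X[r, ] <- random_amplify(fr, tcfg$amp_factor, amp_rng)
      }
      y <- classes[ids]
      logp <- forward(model, X, training = TRUE)
      loss <- nll_loss(logp, y)
      if (!is.finite(loss)) {
        stop("non-finite loss at epoch ", epoch, ", batch ", b,
             " (learning rate too high or degenerate input?)")
      }
      losses[b] <- loss
      dy <- matrix(0, tcfg$batch_size, ncol(logp))
      dy[cbind(seq_len(tcfg$batch_size), y + 1L)] <- -1 / tcfg$batch_size
      backward(model, dy)
      rmsprop_step(model, tcfg$learning_rate, tcfg$rmsprop_alpha, tcfg$eps)
    }
    acc <- NA_real_
    if (!is.null(test_items) && is.finite(tcfg$eval_every) &&
        epoch %% tcfg$eval_every == 0) {
      acc <- evaluate_items(model, test_items)$accuracy
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         loss = mean(losses),
                                         test_accuracy = acc))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f%s", epoch, mean(losses),
                      if (is.na(acc)) "" else sprintf("  test acc %.3f", acc)))
    }
  }
  list(model = model, history = history)
}
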
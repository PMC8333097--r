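#' Network architecture and framing configuration
#'
#' Defaults follow the raw-waveform speaker-identification architecture the
#' classifier is built on: 80 sinc band-pass filters of length 251 in the
#' first convolution; two further convolutions with 60 filters of length 5;
#' layer normalization on the waveform frame and after every convolution;
#' max pooling of length 3 after each convolution; three fully-connected
#' leaky-ReLU layers of 2048 units with batch normalization; and a
#' LogSoftmax output giving per-frame log-posteriors. The frame is 10 ms
#' with a 1 ms shift at 44.1 kHz (441-sample frames).
#'
#' @param frontend `"sinc"` (cut-offs are the only first-layer parameters)
#'   or `"standard_conv"` (free first-layer weights, same shape).
#' @param n_filt_1 First-layer filter count.
#' @param len_filt_1 First-layer kernel length in samples (odd).
#' @param conv_layers List of `c(n_filters, length)` for the remaining
#'   convolutions.
#' @param pool_len Max-pool length after every convolution.
#' @param fc_layers Integer vector of fully-connected layer widths.
#' @param n_classes Number of output classes (>= 2).
#' @param fs Sampling rate in Hz.
#' @param cw_len Frame length in ms.
#' @param cw_shift Frame shift in ms.
#' @param leaky_slope Negative slope of the leaky ReLU.
#' @param dropout Dropout rate applied after each fully-connected layer.
#' @param input_layernorm Layer-normalize each raw frame before the first
#'   convolution.
#' @param seed Seed of the weight-initialization stream.
#' @return Object of class `net_config`.
#' @export
net_config <- function(frontend = c("sinc", "standard_conv"),
                       n_filt_1 = 80, len_filt_1 = 251,
                       conv_layers = list(c(60, 5), c(60, 5)),
                       pool_len = 3, fc_layers = c(2048, 2048, 2048),
                       n_classes = 2, fs = 44100, cw_len = 10, cw_shift = 1,
                       leaky_slope = 0.2, dropout = 0,
                       input_layernorm = TRUE, seed = 42) {
  frontend <- match.arg(frontend)
  stopifnot(n_classes >= 2, n_filt_1 >= 1, len_filt_1 >= 3,
            pool_len >= 1, cw_len > 0, cw_shift > 0)
  if (len_filt_1 %% 2 == 0) stop("len_filt_1 must be odd")
  if (frame_samples(cw_len, fs) < len_filt_1) {
    stop("frame of ", frame_samples(cw_len, fs),
         " samples is shorter than the first-layer kernel (", len_filt_1, ")")
  }
  structure(
    list(frontend = frontend, n_filt_1 = as.integer(n_filt_1),
         len_filt_1 = as.integer(len_filt_1), conv_layers = conv_layers,
         pool_len = as.integer(pool_len), fc_layers = as.integer(fc_layers),
         n_classes = as.integer(n_classes), fs = as.numeric(fs),
         cw_len = cw_len, cw_shift = cw_shift, leaky_slope = leaky_slope,
         dropout = dropout, input_layernorm = input_layernorm,
         seed = as.integer(seed)),
    class = "net_config"
  )
}

#' Write / read a network configuration as YAML
#' @param cfg A [net_config].
#' @param path YAML file path.
#' @return `write_net_config`: `path` invisibly; `read_net_config`: the config.
#' @export
write_net_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_net_config
#' @export
read_net_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$conv_layers <- lapply(x$conv_layers, unlist)
  do.call(net_config, x)
}

#' Build the frame classifier
#'
#' Assembles the layer stack described by a [net_config]. Both frontend
#' variants share every layer except the first convolution's
#' parameterization: the sinc frontend learns 2 numbers per filter (low
#' cut-off, bandwidth), the standard frontend learns the full
#' `n_filt_1 x len_filt_1` kernel matrix. Neither first layer has a bias.
#'
#' @param cfg A [net_config].
#' @return Object of class `sincbird_model`: list with `cfg`, `layers`,
#'   `frame_len`, and the dropout RNG stream.
#' @export
build_model <- function(cfg) {
  rng <- rng_stream(derive_seed(cfg$seed, 7))
  frame_len <- frame_samples(cfg$cw_len, cfg$fs)
  layers <- list()
  add <- function(l) layers[[length(layers) + 1L]] <<- l

  if (isTRUE(cfg$input_layernorm)) add(layer_layernorm(frame_len))

  if (cfg$frontend == "sinc") {
    add(layer_sinc_conv(frame_len, cfg$n_filt_1, cfg$len_filt_1, cfg$fs))
  } else {
    add(layer_conv1d(frame_len, 1L, cfg$n_filt_1, cfg$len_filt_1, rng,
                     bias = FALSE))
  }
  shp <- layers[[length(layers)]]$shape_out # c(L, C)
  conv_blocks <- c(list(NULL), cfg$conv_layers) # first entry: frontend already added
  for (i in seq_along(conv_blocks)) {
    if (i > 1) {
      nf <- conv_blocks[[i]][1]; kl <- conv_blocks[[i]][2]
      add(layer_conv1d(shp[1], shp[2], nf, kl, rng))
      shp <- layers[[length(layers)]]$shape_out
    }
    add(layer_maxpool(shp[1], shp[2], cfg$pool_len))
    shp <- layers[[length(layers)]]$shape_out
    add(layer_layernorm(shp[1] * shp[2]))
    add(layer_leaky_relu(cfg$leaky_slope))
  }

  add(layer_flatten(shp[1], shp[2]))
  n_feat <- shp[1] * shp[2]
  drop_rng <- rng_stream(derive_seed(cfg$seed, 8))
  for (w in cfg$fc_layers) {
    add(layer_linear(n_feat, w, rng))
    add(layer_batchnorm(w))
    add(layer_leaky_relu(cfg$leaky_slope))
    if (cfg$dropout > 0) add(layer_dropout(cfg$dropout, drop_rng))
    n_feat <- w
  }
  add(layer_linear(n_feat, cfg$n_classes, rng))
  add(layer_logsoftmax())

  structure(list(cfg = cfg, layers = layers, frame_len = frame_len),
            class = "sincbird_model")
}

#' Forward pass: frames to log-posteriors
#'
#' @param model A [build_model()] result.
#' @param frames Matrix `(batch, frame_len)` of waveform frames.
#' @param training Use training behaviour (batch statistics, dropout).
#' @return Matrix `(batch, n_classes)` of log-posteriors; each row
#'   exponentiates and sums to one.
#' @export
forward <- function(model, frames, training = FALSE) {
  stopifnot(is.matrix(frames))
  if (ncol(frames) != model$frame_len) {
    stop("frames have ", ncol(frames), " samples; model expects ",
         model$frame_len)
  }
  x <- frames
  for (l in model$layers) x <- l$forward(x, training)
  x
}

# backward pass from d(loss)/d(log-posteriors); fills layer grads
backward <- function(model, dy) {
  for (l in rev(model$layers)) dy <- l$backward(dy)
  invisible(dy)
}

#' Per-layer parameter summary
#'
#' @param model A [sincbird_model].
#' @return data.frame `layer`, `type`, `n_params`.
#' @export
model_summary <- function(model) {
  data.frame(
    layer = seq_along(model$layers),
    type = vapply(model$layers, function(l) l$type, ""),
    n_params = vapply(model$layers, layer_n_params, 0L)
  )
}

#' Learnable parameter counts
#'
#' `frontend_n_params` counts the first convolution only: `2 * n_filt_1`
#' for the sinc frontend (one low cut-off and one bandwidth per filter,
#' independent of kernel length) versus `n_filt_1 * len_filt_1` for the
#' standard frontend.
#'
#' @param model A [sincbird_model].
#' @return Integer count.
#' @export
frontend_n_params <- function(model) {
  ft <- Filter(function(l) l$type %in% c("sinc_conv", "conv1d"), model$layers)[[1]]
  layer_n_params(ft)
}

#' @rdname frontend_n_params
#' @export
total_n_params <- function(model) {
  sum(vapply(model$layers, layer_n_params, 0L))
}

#' Save / load model weights
#'
#' Serializes every layer's parameters (plus batch-norm running statistics)
#' to an RDS file; the architecture itself is rebuilt from the stored
#' config.
#'
#' @param model A [sincbird_model].
#' @param path Checkpoint path (`.rds`).
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(model, path) {
  state <- lapply(model$layers, function(l) {
    s <- list(params = l$params)
    if (l$type == "batchnorm") {
      s$run_mean <- l$run_mean
      s$run_var <- l$run_var
    }
    s
  })
  saveRDS(list(cfg = model$cfg, state = state), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  model <- build_model(do.call(net_config, unclass(x$cfg)))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    l$params <- x$state[[i]]$params
    if (l$type == "batchnorm") {
      l$run_mean <- x$state[[i]]$run_mean
      l$run_var <- x$state[[i]]$run_var
    }
  }
  model
}
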
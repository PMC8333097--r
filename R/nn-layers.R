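# Minimal feed-forward layer engine with hand-derived backpropagation.
#
# Layers are environments carrying `params` (named numeric arrays), `grads`
# (same shapes, filled by backward), a `forward(x, training)` and a
# `backward(dy)` closure. Shapes through the convolutional stage are
# (batch, length, channels) arrays; fully-connected stages use
# (batch, features) matrices. All heavy lifting is BLAS matrix products via
# an im2col layout, so a CPU handles the scaled-down configurations at
# interactive speed.

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  e$opt <- list()
  e
}

.as_bLC <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  x
}

# ---- convolution ------------------------------------------------------------

# idx vector enumerating (t, k, c) with t fastest: column (c-1)*L + (t+k-1)
.conv_idx <- function(L, K, C) {
  out_len <- L - K + 1L
  t <- seq_len(out_len)
  idx <- integer(out_len * K * C)
  pos <- 1L
  for (c in seq_len(C)) {
    for (k in seq_len(K)) {
      idx[pos:(pos + out_len - 1L)] <- (c - 1L) * L + (t + k - 1L)
      pos <- pos + out_len
    }
  }
  idx
}

conv_forward <- function(x, W, bias, idx, L, K, C) {
  x <- .as_bLC(x)
  B <- dim(x)[1L]
  out_len <- L - K + 1L
  dim(x) <- c(B, L * C)
  M <- x[, idx, drop = FALSE]
  dim(M) <- c(B * out_len, K * C)
  Y <- M %*% W
  if (!is.null(bias)) Y <- sweep(Y, 2L, bias, "+")
  dim(Y) <- c(B, out_len, ncol(W))
  list(Y = Y, M = M)
}

conv_backward <- function(dy, M, W, L, K, C, B, out_len) {
  Fn <- ncol(W)
  dim(dy) <- c(B * out_len, Fn)
  dW <- crossprod(M, dy)
  db <- colSums(dy)
  dM <- dy %*% t(W)
  dim(dM) <- c(B, out_len, K, C)
  dx <- matrix(0, B, L * C)
  for (c in seq_len(C)) {
    off <- (c - 1L) * L
    for (k in seq_len(K)) {
      cols <- off + (k:(k + out_len - 1L))
      dx[, cols] <- dx[, cols] + dM[, , k, c]
    }
  }
  dim(dx) <- c(B, L, C)
  list(dx = dx, dW = dW, db = db)
}

#' @noRd
layer_conv1d <- function(L_in, in_ch, n_filt, kernel_len, rng, bias = TRUE) {
  e <- new_layer("conv1d")
  e$L <- as.integer(L_in); e$C <- as.integer(in_ch)
  e$K <- as.integer(kernel_len); e$Fn <- as.integer(n_filt)
  e$out_len <- e$L - e$K + 1L
  if (e$out_len < 1L) stop("conv input length ", L_in, " shorter than kernel ", kernel_len)
  e$idx <- .conv_idx(e$L, e$K, e$C)
  lim <- sqrt(6 / (e$K * e$C))
  e$params$W <- matrix(rng$runif(e$K * e$C * e$Fn, -lim, lim), e$K * e$C, e$Fn)
  if (bias) e$params$b <- numeric(e$Fn)
  e$forward <- function(x, training = FALSE) {
    x <- .as_bLC(x)
    e$B <- dim(x)[1L]
    r <- conv_forward(x, e$params$W, e$params$b, e$idx, e$L, e$K, e$C)
    e$M <- r$M
    r$Y
  }
  e$backward <- function(dy) {
    r <- conv_backward(dy, e$M, e$params$W, e$L, e$K, e$C, e$B, e$out_len)
    e$grads$W <- r$dW
    if (!is.null(e$params$b)) e$grads$b <- r$db
    e$M <- NULL
    r$dx
  }
  e$shape_out <- c(e$out_len, e$Fn)
  e
}

# first layer parameterized by sinc cut-offs: two learnable numbers per filter
#' @noRd
layer_sinc_conv <- function(L_in, n_filt, kernel_len, fs, rng = NULL, f_min = 0) {
  e <- new_layer("sinc_conv")
  e$L <- as.integer(L_in); e$C <- 1L
  e$K <- as.integer(kernel_len); e$Fn <- as.integer(n_filt)
  e$fs <- fs
  e$out_len <- e$L - e$K + 1L
  if (e$out_len < 1L) stop("conv input length ", L_in, " shorter than kernel ", kernel_len)
  e$idx <- .conv_idx(e$L, e$K, e$C)
  init <- mel_init(n_filt, fs, f_min)
  e$params$p_low <- init$f_l
  e$params$p_band <- init$f_h - init$f_l
  e$window <- hamming_window(kernel_len)
  e$materialize <- function() {
    co <- effective_cutoffs(e$params$p_low, e$params$p_band, e$fs)
    W <- matrix(0, e$K, e$Fn)
    for (j in seq_len(e$Fn)) {
      W[, j] <- build_sinc_kernel(co$f_l[j], co$f_h[j], e$K, e$fs)
    }
    W
  }
  e$forward <- function(x, training = FALSE) {
    x <- .as_bLC(x)
    e$B <- dim(x)[1L]
    e$W <- e$materialize()
    r <- conv_forward(x, e$W, NULL, e$idx, e$L, e$K, e$C)
    e$M <- r$M
    r$Y
  }
  e$backward <- function(dy) {
    r <- conv_backward(dy, e$M, e$W, e$L, e$K, e$C, e$B, e$out_len)
    co <- effective_cutoffs(e$params$p_low, e$params$p_band, e$fs)
    half_nyq <- e$fs / 2
    dpl <- numeric(e$Fn); dpb <- numeric(e$Fn)
    for (j in seq_len(e$Fn)) {
      gKfl <- .kernel_grad_wrt_cutoff(co$f_l[j], e$K, e$fs) * (-1)
      gKfh <- .kernel_grad_wrt_cutoff(co$f_h[j], e$K, e$fs)
      dfl <- sum(r$dW[, j] * gKfl)
      dfh <- sum(r$dW[, j] * gKfh)
      # chain through the |.| + clip constraint mapping (subgradients)
      low_free <- abs(e$params$p_low[j]) < half_nyq
      high_free <- co$f_l[j] + abs(e$params$p_band[j]) < half_nyq
      s_low <- sign(e$params$p_low[j]); s_band <- sign(e$params$p_band[j])
      dpl[j] <- s_low * low_free * (dfl + dfh * high_free)
      dpb[j] <- s_band * high_free * dfh
    }
    e$grads$p_low <- dpl
    e$grads$p_band <- dpb
    e$M <- NULL
    r$dx
  }
  e$shape_out <- c(e$out_len, e$Fn)
  e
}

# ---- pooling, normalization, activations ------------------------------------

#' @noRd
layer_maxpool <- function(L_in, C, pool_len) {
  e <- new_layer("maxpool")
  e$L <- as.integer(L_in); e$C <- as.integer(C); e$p <- as.integer(pool_len)
  e$Lout <- e$L %/% e$p
  if (e$Lout < 1L) stop("pool length ", pool_len, " exceeds input length ", L_in)
  e$forward <- function(x, training = FALSE) {
    x <- .as_bLC(x)
    B <- dim(x)[1L]; e$B <- B
    Lt <- e$Lout * e$p
    A <- x[, seq_len(Lt), , drop = FALSE]
    dim(A) <- c(B, e$p, e$Lout, e$C)
    Q <- aperm(A, c(1L, 3L, 4L, 2L))
    dim(Q) <- c(B * e$Lout * e$C, e$p)
    mx <- Q[, 1L]; arg <- rep(1L, nrow(Q))
    for (j in 2:e$p) {
      upd <- Q[, j] > mx
      mx[upd] <- Q[upd, j]
      arg[upd] <- j
    }
    e$arg <- arg
    dim(mx) <- c(B, e$Lout, e$C)
    mx
  }
  e$backward <- function(dy) {
    B <- e$B
    n <- B * e$Lout * e$C
    dQ <- matrix(0, n, e$p)
    dQ[cbind(seq_len(n), e$arg)] <- as.vector(dy)
    dim(dQ) <- c(B, e$Lout, e$C, e$p)
    dx_t <- aperm(dQ, c(1L, 4L, 2L, 3L))
    dim(dx_t) <- c(B, e$Lout * e$p, e$C)
    if (e$Lout * e$p < e$L) {
      dx <- array(0, c(B, e$L, e$C))
      dx[, seq_len(e$Lout * e$p), ] <- dx_t
      dx
    } else {
      dx_t
    }
  }
  e$shape_out <- c(e$Lout, e$C)
  e
}

# layer normalization over all features of one sample, per-feature affine
#' @noRd
layer_layernorm <- function(n_feat, eps = 1e-5) {
  e <- new_layer("layernorm")
  e$Fn <- as.integer(n_feat); e$eps <- eps
  e$params$g <- rep(1, n_feat)
  e$params$b <- numeric(n_feat)
  e$forward <- function(x, training = FALSE) {
    e$in_dim <- dim(x)
    if (length(e$in_dim) == 3L) dim(x) <- c(e$in_dim[1L], e$Fn)
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc * xc)
    e$ivar <- 1 / sqrt(v + e$eps)
    e$xhat <- xc * e$ivar
    y <- sweep(sweep(e$xhat, 2L, e$params$g, "*"), 2L, e$params$b, "+")
    if (length(e$in_dim) == 3L) dim(y) <- e$in_dim
    y
  }
  e$backward <- function(dy) {
    dim(dy) <- c(length(dy) %/% e$Fn, e$Fn)
    e$grads$g <- colSums(dy * e$xhat)
    e$grads$b <- colSums(dy)
    dxh <- sweep(dy, 2L, e$params$g, "*")
    Fh <- e$Fn
    dx <- (e$ivar / Fh) * (Fh * dxh - rowSums(dxh) - e$xhat * rowSums(dxh * e$xhat))
    if (length(e$in_dim) == 3L) dim(dx) <- e$in_dim
    e$xhat <- NULL
    dx
  }
  e$shape_out <- n_feat
  e
}

# batch normalization over the batch, per feature (fully-connected stage)
#' @noRd
layer_batchnorm <- function(n_feat, eps = 1e-5, momentum = 0.1) {
  e <- new_layer("batchnorm")
  e$Fn <- as.integer(n_feat); e$eps <- eps; e$momentum <- momentum
  e$params$g <- rep(1, n_feat)
  e$params$b <- numeric(n_feat)
  e$run_mean <- numeric(n_feat)
  e$run_var <- rep(1, n_feat)
  e$forward <- function(x, training = FALSE) {
    if (training) {
      mu <- colMeans(x)
      xc <- sweep(x, 2L, mu)
      v <- colMeans(xc * xc)
      e$ivar <- 1 / sqrt(v + e$eps)
      e$xhat <- sweep(xc, 2L, e$ivar, "*")
      e$run_mean <- (1 - e$momentum) * e$run_mean + e$momentum * mu
      e$run_var <- (1 - e$momentum) * e$run_var + e$momentum * v
      sweep(sweep(e$xhat, 2L, e$params$g, "*"), 2L, e$params$b, "+")
    } else {
      xhat <- sweep(sweep(x, 2L, e$run_mean), 2L, 1 / sqrt(e$run_var + e$eps), "*")
      sweep(sweep(xhat, 2L, e$params$g, "*"), 2L, e$params$b, "+")
    }
  }
  e$backward <- function(dy) {
    n <- nrow(dy)
    e$grads$g <- colSums(dy * e$xhat)
    e$grads$b <- colSums(dy)
    dxh <- sweep(dy, 2L, e$params$g, "*")
    t1 <- sweep(dxh, 2L, colMeans(dxh))
    t2 <- sweep(e$xhat, 2L, colMeans(dxh * e$xhat), "*")
    dx <- sweep(t1 - t2, 2L, e$ivar, "*")
    e$xhat <- NULL
    dx
  }
  e$shape_out <- n_feat
  e
}

#' @noRd
layer_leaky_relu <- function(slope = 0.2) {
  e <- new_layer("leaky_relu")
  e$slope <- slope
  e$forward <- function(x, training = FALSE) {
    m <- e$slope + (1 - e$slope) * (x > 0)
    dim(m) <- dim(x)
    e$m <- m
    x * m
  }
  e$backward <- function(dy) {
    dx <- dy * e$m
    e$m <- NULL
    dx
  }
  e
}

#' @noRd
layer_flatten <- function(L, C) {
  e <- new_layer("flatten")
  e$L <- as.integer(L); e$C <- as.integer(C)
  e$forward <- function(x, training = FALSE) {
    x <- .as_bLC(x)
    dim(x) <- c(dim(x)[1L], e$L * e$C)
    x
  }
  e$backward <- function(dy) {
    dim(dy) <- c(nrow(dy), e$L, e$C)
    dy
  }
  e$shape_out <- L * C
  e
}

#' @noRd
layer_linear <- function(n_in, n_out, rng) {
  e <- new_layer("linear")
  lim <- sqrt(6 / n_in)
  e$params$W <- matrix(rng$runif(n_in * n_out, -lim, lim), n_in, n_out)
  e$params$b <- numeric(n_out)
  e$forward <- function(x, training = FALSE) {
    e$x <- x
    sweep(x %*% e$params$W, 2L, e$params$b, "+")
  }
  e$backward <- function(dy) {
    e$grads$W <- crossprod(e$x, dy)
    e$grads$b <- colSums(dy)
    dx <- dy %*% t(e$params$W)
    e$x <- NULL
    dx
  }
  e$shape_out <- n_out
  e
}

#' @noRd
layer_dropout <- function(rate, rng) {
  e <- new_layer("dropout")
  e$rate <- rate
  e$rng <- rng
  e$forward <- function(x, training = FALSE) {
    if (!training || e$rate <= 0) return(x)
    m <- (e$rng$runif(length(x)) >= e$rate) / (1 - e$rate)
    dim(m) <- dim(x)
    e$m <- m
    x * m
  }
  e$backward <- function(dy) {
    if (is.null(e$m)) return(dy)
    dx <- dy * e$m
    e$m <- NULL
    dx
  }
  e
}

#' @noRd
layer_logsoftmax <- function() {
  e <- new_layer("logsoftmax")
  e$forward <- function(x, training = FALSE) {
    y <- x - row_logsumexp(x)
    e$y <- y
    y
  }
  e$backward <- function(dy) {
    dx <- dy - exp(e$y) * rowSums(dy)
    e$y <- NULL
    dx
  }
  e
}

layer_n_params <- function(layer) {
  sum(vapply(layer$params, length, 0L))
}
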
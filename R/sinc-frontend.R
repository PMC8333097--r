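#' Cardinal sine
#'
#' `sinc(x) = sin(x) / x`, with `sinc(0) = 1` by continuity.
#' @param x Numeric vector.
#' @return Numeric vector.
#' @export
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

# textbook Hamming taper of length n
hamming_window <- function(n) {
  m <- 0:(n - 1)
  0.54 - 0.46 * cos(2 * pi * m / (n - 1))
}

#' Build a Hamming-smoothed sinc band-pass kernel
#'
#' The kernel is the difference of two low-pass sinc kernels,
#' `g[n] = 2 f_h sinc(2 pi f_h n) - 2 f_l sinc(2 pi f_l n)` with frequencies
#' normalized by the sampling rate and sample index `n` centred on zero,
#' multiplied elementwise by a Hamming window. The result is an FIR
#' band-pass with (ideal) pass band `(f_l, f_h)`, symmetric about its
#' centre tap; `f_l = f_h` yields the all-zero kernel.
#'
#' @param f_l Low cut-off in Hz, `0 <= f_l <= f_h`.
#' @param f_h High cut-off in Hz, `f_h <= fs/2`.
#' @param kernel_len Odd kernel length in samples.
#' @param fs Sampling rate in Hz.
#' @param window Apply the Hamming taper (default TRUE).
#' @return Numeric kernel of length `kernel_len`.
#' @export
build_sinc_kernel <- function(f_l, f_h, kernel_len, fs, window = TRUE) {
  if (kernel_len %% 2 == 0) stop("kernel_len must be odd")
  if (f_l > f_h) stop("f_l must not exceed f_h")
  if (f_l < 0 || f_h > fs / 2) stop("cut-offs must lie in [0, fs/2]")
  half <- (kernel_len - 1) / 2
  n <- -half:half
  fl <- f_l / fs
  fh <- f_h / fs
  g <- 2 * fh * sinc(2 * pi * fh * n) - 2 * fl * sinc(2 * pi * fl * n)
  if (window) g <- g * hamming_window(kernel_len)
  g
}

#' Map unconstrained filter parameters to valid cut-off frequencies
#'
#' Gradient steps can drive the raw per-filter parameters anywhere on the
#' real line; this total, continuous mapping always returns a valid band:
#' `f_l = |p_low|`, `f_h = f_l + |p_band|`, both clipped to `[0, fs/2]`.
#'
#' @param p_low,p_band Numeric vectors of raw parameters (Hz scale).
#' @param fs Sampling rate in Hz.
#' @return List with numeric vectors `f_l` and `f_h`,
#'   `0 <= f_l <= f_h <= fs/2` elementwise.
#' @export
effective_cutoffs <- function(p_low, p_band, fs) {
  f_l <- pmin(abs(p_low), fs / 2)
  f_h <- pmin(f_l + abs(p_band), fs / 2)
  list(f_l = f_l, f_h = f_h)
}

#' Mel-scale frequency conversions
#'
#' `mel(f) = 2595 log10(1 + f/700)` and its inverse.
#' @param f Frequency in Hz.
#' @param m Mel value.
#' @return Numeric vector.
#' @export
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel-scale initial cut-off frequencies for a filter bank
#'
#' `n_filt + 1` points equally spaced on the mel scale between
#' `mel(f_min)` and `mel(fs/2)`; adjacent points form each filter's
#' `(f_l, f_h)`, giving contiguous, strictly increasing bands covering
#' `[f_min, fs/2]`.
#'
#' @param n_filt Number of filters (>= 1).
#' @param fs Sampling rate in Hz.
#' @param f_min Lowest edge in Hz (default 0).
#' @return data.frame with columns `f_l`, `f_h` (one row per filter).
#' @export
mel_init <- function(n_filt, fs, f_min = 0) {
  stopifnot(n_filt >= 1)
  if (f_min >= fs / 2) stop("f_min must be below fs/2")
  pts <- mel_to_hz(seq(hz_to_mel(f_min), hz_to_mel(fs / 2), length.out = n_filt + 1))
  pts[1] <- f_min
  pts[n_filt + 1] <- fs / 2 # guard round-trip rounding at the edges
  data.frame(f_l = pts[-(n_filt + 1)], f_h = pts[-1])
}

#' Create a learnable sinc filter bank
#'
#' Holds the raw per-filter parameters `(p_low, p_band)` — two per filter,
#' independent of kernel length — from which effective cut-offs derive via
#' [effective_cutoffs()]. Initialized on the mel scale.
#'
#' @param n_filt Number of filters.
#' @param kernel_len Odd kernel length in samples.
#' @param fs Sampling rate in Hz.
#' @param f_min Lowest mel-init edge in Hz.
#' @return Object of class `sinc_filter_bank`: list with `n_filt`,
#'   `kernel_len`, `fs`, `p_low`, `p_band`, `window`.
#' @export
sinc_filter_bank <- function(n_filt, kernel_len, fs, f_min = 0) {
  if (kernel_len %% 2 == 0) stop("kernel_len must be odd")
  init <- mel_init(n_filt, fs, f_min)
  structure(
    list(n_filt = as.integer(n_filt), kernel_len = as.integer(kernel_len),
         fs = as.numeric(fs),
         p_low = init$f_l, p_band = init$f_h - init$f_l,
         window = hamming_window(kernel_len)),
    class = "sinc_filter_bank"
  )
}

#' Materialize the FIR kernels of a sinc filter bank
#'
#' @param bank A [sinc_filter_bank].
#' @return Matrix `kernel_len x n_filt`; column j is filter j's kernel.
#' @export
bank_kernels <- function(bank) {
  co <- effective_cutoffs(bank$p_low, bank$p_band, bank$fs)
  k <- matrix(0, bank$kernel_len, bank$n_filt)
  for (j in seq_len(bank$n_filt)) {
    k[, j] <- build_sinc_kernel(co$f_l[j], co$f_h[j], bank$kernel_len, bank$fs)
  }
  k
}

# partial derivatives of the windowed kernel w.r.t. f_l and f_h (Hz):
# d/df [ 2 (f/fs) sinc(2 pi (f/fs) n) ] = (2/fs) cos(2 pi (f/fs) n)
.kernel_grad_wrt_cutoff <- function(f, kernel_len, fs) {
  half <- (kernel_len - 1) / 2
  n <- -half:half
  (2 / fs) * cos(2 * pi * (f / fs) * n) * hamming_window(kernel_len)
}

#' Convolve a waveform chunk with every filter of a bank
#'
#' Direct FIR filtering over the valid region (no padding): output sample
#' `t` of filter `j` is `sum_i x[t + i - 1] * k_j[i]`. Because the sinc
#' kernels are even-symmetric this cross-correlation convention coincides
#' with convolution; the impulse response therefore reproduces the kernel.
#'
#' @param x Numeric waveform chunk, `length(x) >= kernel_len`.
#' @param bank A [sinc_filter_bank], or a kernel matrix from [bank_kernels()].
#' @return Matrix `(length(x) - kernel_len + 1) x n_filt` of filtered
#'   channels.
#' @export
filter_bank_convolve <- function(x, bank) {
  kern <- if (inherits(bank, "sinc_filter_bank")) bank_kernels(bank) else bank
  I <- nrow(kern)
  N <- length(x)
  if (N < I) stop("chunk shorter than kernel (", N, " < ", I, ")")
  out_len <- N - I + 1
  idx <- outer(seq_len(out_len), seq_len(I) - 1L, `+`)
  xcol <- matrix(x[idx], out_len, I)
  xcol %*% kern
}

#' Frequency response of every filter in a bank
#'
#' Returns the materialized time-domain kernels and their FFT magnitude
#' spectra, ready for plotting; the peak frequency of a well-formed filter
#' lies inside its effective band.
#'
#' @param bank A [sinc_filter_bank].
#' @param n_fft FFT length (default: next power of two >= 8x kernel length).
#' @return List with `freq` (Hz), `kernels` (`kernel_len x n_filt`),
#'   `magnitude` (`n_fft/2 x n_filt`), `peak_freq` (Hz per filter), and the
#'   effective `f_l`, `f_h`.
#' @export
frequency_response <- function(bank, n_fft = NULL) {
  kern <- bank_kernels(bank)
  if (is.null(n_fft)) n_fft <- 2^ceiling(log2(8 * bank$kernel_len))
  nb <- n_fft %/% 2
  mag <- matrix(0, nb, bank$n_filt)
  for (j in seq_len(bank$n_filt)) {
    z <- c(kern[, j], rep(0, n_fft - bank$kernel_len))
    mag[, j] <- Mod(stats::fft(z))[seq_len(nb)]
  }
  freq <- (seq_len(nb) - 1) / n_fft * bank$fs
  co <- effective_cutoffs(bank$p_low, bank$p_band, bank$fs)
  peak <- freq[apply(mag, 2L, which.max)]
  list(freq = freq, kernels = kern, magnitude = mag, peak_freq = peak,
       f_l = co$f_l, f_h = co$f_h)
}

#' Save / load a sinc filter bank as JSON
#'
#' @param bank A [sinc_filter_bank].
#' @param path JSON path.
#' @return `write_bank`: `path` invisibly; `read_bank`: the bank.
#' @export
write_bank <- function(bank, path) {
  jsonlite::write_json(unclass(bank)[c("n_filt", "kernel_len", "fs",
                                       "p_low", "p_band")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bank
#' @export
read_bank <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  b <- sinc_filter_bank(x$n_filt, x$kernel_len, x$fs)
  b$p_low <- as.numeric(x$p_low)
  b$p_band <- as.numeric(x$p_band)
  b
}
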
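#' Number of analysis frames that fit a signal
#'
#' With window length `w` and shift `s` (both in samples), a signal of `n`
#' samples yields `floor((n - w) / s) + 1` frames, or zero when `n < w`.
#'
#' @param n Signal length in samples.
#' @param w Window (frame) length in samples.
#' @param s Frame shift in samples.
#' @return Integer frame count.
#' @export
n_frames <- function(n, w, s) {
  stopifnot(w >= 1, s >= 1)
  ifelse(n < w, 0L, as.integer((n - w) %/% s) + 1L)
}

#' Frame length in samples for a window given in milliseconds
#'
#' @param cw_len Window length in milliseconds.
#' @param fs Sampling frequency in Hz.
#' @return Integer number of samples, `round(cw_len * fs / 1000)`.
#' @export
frame_samples <- function(cw_len, fs) {
  as.integer(round(cw_len * fs / 1000))
}

# log-sum-exp over rows of a matrix, numerically stable
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
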
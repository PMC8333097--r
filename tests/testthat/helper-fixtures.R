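# Shared fixtures and independent oracles.

# Direct evaluation of the FIR sum y[t] = sum_i x[t+i-1] * k[i], one output
# sample at a time; the independent reference for the im2col implementation.
brute_force_convolve <- function(x, kernels) {
  I <- nrow(kernels)
  out_len <- length(x) - I + 1
  y <- matrix(0, out_len, ncol(kernels))
  for (j in seq_len(ncol(kernels))) {
    k <- kernels[, j]
    for (t in seq_len(out_len)) {
      y[t, j] <- sum(x[t:(t + I - 1)] * k)
    }
  }
  y
}

# Exhaustive pairwise rank statistic for binary AUC: ties count 1/2.
brute_force_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# fraction of spectral energy of a signal inside [lo, hi] Hz
band_energy_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  half <- sp[seq_len(n %/% 2)]
  freq <- (seq_len(n %/% 2) - 1) / n * fs
  sum(half[freq >= lo & freq <= hi]) / sum(half)
}

spectral_centroid <- function(x, fs) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  half <- sp[seq_len(n %/% 2)]
  freq <- (seq_len(n %/% 2) - 1) / n * fs
  sum(freq * half) / sum(half)
}

# a small labeled corpus reused by labels-io and pipeline tests
tiny_corpus <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$res)) {
      dir <- file.path(tempdir(), "sincbird_tiny_corpus")
      spec <- corpus_spec(n_species = 3, files_per_class = 4,
                          file_len_range = c(0.4, 0.7), fs = 8000,
                          events_per_file = 2, overlap_prob = 0.3,
                          noise_snr_db = 12, include_nuisance = TRUE,
                          nuisance_prob = 0.3, seed = 11)
      man <- make_corpus(spec, dir)
      cache$res <- list(dir = dir, spec = spec, manifest = man)
    }
    cache$res
  }
})

# the CPU-scale band-separated benchmark, trained once per session for both
# frontends and three seeds; reused by the acceptance checks
benchmark_runs <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$res)) {
      wd <- file.path(tempdir(), "sincbird_benchmark")
      seeds <- c(1, 2, 3)
      res <- list()
      for (fe in c("sinc", "standard_conv")) {
        res[[fe]] <- lapply(seeds, function(s) {
          run_benchmark(fe, seed = s, work_dir = wd)
        })
      }
      cache$res <- res
    }
    cache$res
  }
})
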
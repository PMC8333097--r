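test_that("sinc kernel degenerate and structural cases", {
  expect_error(build_sinc_kernel(1000, 2000, 250, 44100), "odd")
  expect_error(build_sinc_kernel(3000, 2000, 251, 44100), "exceed")

  # equal cut-offs cancel identically
  expect_equal(build_sinc_kernel(1500, 1500, 129, 44100), rep(0, 129))

  # centre tap: 2 (f_h - f_l)/fs scaled by the window centre value
  k <- build_sinc_kernel(2000, 4000, 251, 44100)
  w_centre <- 0.54 - 0.46 * cos(2 * pi * 125 / 250)
  expect_equal(k[126], 2 * (4000 - 2000) / 44100 * w_centre)
  expect_equal(k, rev(k)) # even symmetry
})

test_that("built kernel is a band-pass filter (FFT oracle)", {
  fs <- 44100
  k <- build_sinc_kernel(2000, 4000, 251, fs)
  n_fft <- 8192
  mag <- Mod(stats::fft(c(k, rep(0, n_fft - length(k)))))[1:(n_fft / 2)]
  freq <- (0:(n_fft / 2 - 1)) / n_fft * fs
  pk <- freq[which.max(mag)]
  expect_gte(pk, 2000)
  expect_lte(pk, 4000)
  stop_mag <- mag[which.min(abs(freq - 8000))]
  expect_lt(20 * log10(stop_mag / max(mag)), -20)
})

test_that("cut-off constraint mapping is total and correct", {
  fs <- 16000
  co <- effective_cutoffs(-100, 50, fs)
  expect_equal(co$f_l, 100)
  expect_equal(co$f_h, 150)
  co <- effective_cutoffs(0, fs, fs)
  expect_equal(co$f_h, fs / 2)

  r <- rng_stream(42)
  p1 <- r$rnorm(1e4, sd = 2e4)
  p2 <- r$rnorm(1e4, sd = 2e4)
  co <- effective_cutoffs(p1, p2, fs)
  expect_true(all(co$f_l >= 0))
  expect_true(all(co$f_l <= co$f_h))
  expect_true(all(co$f_h <= fs / 2))
})

test_that("mel initialization matches an independent mel-spacing computation", {
  expect_error(mel_init(4, 16000, f_min = 9000), "below fs/2")

  # one filter spans the whole range
  m1 <- mel_init(1, 16000, f_min = 50)
  expect_equal(m1$f_l, 50)
  expect_equal(m1$f_h, 8000)

  m <- mel_init(80, 16000, f_min = 0)
  # contiguous, strictly increasing bands inside [0, fs/2]
  expect_equal(m$f_l[-1], m$f_h[-80])
  expect_true(all(diff(m$f_l) > 0))
  expect_true(all(m$f_l >= 0 & m$f_h <= 8000))

  # independent recomputation of the mel points
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(v) 700 * (10^(v / 2595) - 1)
  pts <- imel(seq(mel(0), mel(8000), length.out = 81))
  expect_equal(m$f_l, pts[1:80], tolerance = 1e-10)
  expect_equal(m$f_h, pts[2:81], tolerance = 1e-10)
})

test_that("filter-bank convolution equals the direct FIR sum", {
  r <- rng_stream(7)
  for (I in c(65, 129, 251)) {
    n <- 300 + round(r$runif(1, 0, 1700))
    x <- r$rnorm(n)
    bank <- sinc_filter_bank(3, I, 16000, f_min = 100)
    # perturb the parameters so the kernels are not just the mel init
    bank$p_low <- bank$p_low * r$runif(3, 0.5, 1.5)
    bank$p_band <- bank$p_band * r$runif(3, 0.5, 1.5)
    y <- filter_bank_convolve(x, bank)
    y0 <- brute_force_convolve(x, bank_kernels(bank))
    expect_lt(max(abs(y - y0)) / max(abs(y0)), 1e-10)
  }
  expect_error(filter_bank_convolve(rnorm(50), sinc_filter_bank(2, 65, 16000)),
               "shorter than kernel")
})

test_that("impulse response reproduces the kernel and tones are band-selected", {
  bank <- sinc_filter_bank(1, 65, 16000, f_min = 2000)
  bank$p_low <- 3000; bank$p_band <- 2000 # band 3-5 kHz
  x <- numeric(200); x[100] <- 1
  y <- filter_bank_convolve(x, bank)
  k <- bank_kernels(bank)[, 1]
  # the kernel appears (reversed by the cross-correlation convention; it is
  # symmetric, so identically) around the impulse
  expect_equal(y[36:100, 1], k, tolerance = 1e-12)

  fs <- 16000
  t <- (0:3999) / fs
  in_band <- sin(2 * pi * 4000 * t)
  out_band <- sin(2 * pi * 1000 * t)
  rms <- function(v) sqrt(mean(v^2))
  expect_gt(rms(filter_bank_convolve(in_band, bank)) /
              rms(filter_bank_convolve(out_band, bank)), 10)
})

test_that("frequency responses peak inside their bands, in order", {
  bank <- sinc_filter_bank(20, 129, 16000, f_min = 200)
  fr <- frequency_response(bank, n_fft = 16384)
  expect_true(all(fr$peak_freq >= fr$f_l - 16000 / 16384))
  expect_true(all(fr$peak_freq <= fr$f_h + 16000 / 16384))
  expect_true(all(diff(fr$peak_freq) > 0))
  # response equals the FFT of the built kernel by construction
  expect_equal(fr$kernels[, 3],
               build_sinc_kernel(fr$f_l[3], fr$f_h[3], 129, 16000))

  # zero-band filter: flat zero spectrum
  b0 <- sinc_filter_bank(1, 65, 16000)
  b0$p_low <- 1000; b0$p_band <- 0
  expect_equal(max(frequency_response(b0)$magnitude), 0)
})

test_that("bank serialization round-trips", {
  bank <- sinc_filter_bank(8, 65, 22050, f_min = 50)
  bank$p_low[3] <- -123.4
  f <- withr::local_tempfile(fileext = ".json")
  write_bank(bank, f)
  b2 <- read_bank(f)
  expect_equal(b2$p_low, bank$p_low)
  expect_equal(b2$p_band, bank$p_band)
  expect_equal(b2$kernel_len, bank$kernel_len)
  expect_equal(bank_kernels(b2), bank_kernels(bank))
})

test_that("sinc-layer gradients match finite differences", {
  cfg <- net_config(frontend = "sinc", n_filt_1 = 4, len_filt_1 = 33,
                    conv_layers = list(c(4, 5)), pool_len = 2,
                    fc_layers = c(16), n_classes = 3, fs = 8000,
                    cw_len = 10, cw_shift = 5, seed = 9)
  model <- build_model(cfg)
  r <- rng_stream(3)
  X <- matrix(r$rnorm(6 * model$frame_len), 6)
  y <- c(0L, 1L, 2L, 0L, 1L, 2L)
  loss <- function() {
    lp <- forward(model, X, training = TRUE)
    -mean(lp[cbind(1:6, y + 1L)])
  }
  lp <- forward(model, X, training = TRUE)
  dy <- matrix(0, 6, 3)
  dy[cbind(1:6, y + 1L)] <- -1 / 6
  sincbird:::backward(model, dy)
  sl <- Filter(function(l) l$type == "sinc_conv", model$layers)[[1]]

  eps <- 1e-3
  for (nm in c("p_low", "p_band")) {
    for (j in c(1L, 3L)) {
      p0 <- sl$params[[nm]][j]
      sl$params[[nm]][j] <- p0 + eps
      up <- loss()
      sl$params[[nm]][j] <- p0 - eps
      dn <- loss()
      sl$params[[nm]][j] <- p0
      fd <- (up - dn) / (2 * eps)
      an <- sl$grads[[nm]][j]
      expect_lt(abs(an - fd) / max(abs(fd), 1e-8), 1e-3)
    }
  }
})
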
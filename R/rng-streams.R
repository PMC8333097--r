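#' Independent named random-number streams
#'
#' Experiments in this package draw randomness from several independent
#' sources (corpus synthesis, train/test splitting, frame-window sampling,
#' random amplification, weight initialization). Giving each source its own
#' stream means an ablation that disables one source (e.g. amplification)
#' leaves the draws of every other source unchanged for a shared master seed.
#'
#' A stream is a closure around a private copy of R's RNG state; drawing from
#' it never touches the global `.Random.seed`.
#'
#' @param seed Integer seed for this stream.
#' @return An object of class `rng_stream` with methods `runif`, `rnorm`,
#'   `sample_int`, and `sample`.
#' @examples
#' r <- rng_stream(1)
#' r$runif(3)
#' @export
rng_stream <- function(seed) {
  seed <- as.integer(seed)
  state <- local({
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
    s <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    s
  })

  draw <- function(fn) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    fn()
  }

  obj <- list(
    seed = seed,
    runif = function(n, min = 0, max = 1) draw(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) draw(function() stats::rnorm(n, mean, sd)),
    sample_int = function(n, size = 1, replace = FALSE, prob = NULL)
      draw(function() sample.int(n, size, replace = replace, prob = prob)),
    sample = function(x, size, replace = FALSE, prob = NULL)
      draw(function() sample(x, size, replace = replace, prob = prob))
  )
  class(obj) <- "rng_stream"
  obj
}

#' Derive a child seed from a master seed
#'
#' Deterministic, collision-avoiding mapping used to give each named stream
#' of an experiment its own seed; result always fits a 32-bit integer.
#'
#' @param seed Master integer seed.
#' @param k Stream index (0, 1, 2, ...).
#' @return Integer child seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 1000003) %% 2147483563) + 1L
}
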
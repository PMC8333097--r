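#' Species call template
#'
#' Describes how calls of one synthetic class sound: a carrier band, a
#' harmonic stack, a linear chirp, and uniform duration bounds. Rendered
#' calls keep (near) all of their energy inside `carrier_band`, which makes
#' classes spectrally separable the way tonal bird syllables are.
#'
#' @param name Class tag, conventionally `"<Species>_<kind>"` (e.g. `"Sp01_song"`).
#' @param carrier_band Numeric `(low, high)` in Hz, `0 < low < high`.
#' @param n_harmonics Integer >= 0; harmonics above the fundamental, all kept
#'   inside the carrier band.
#' @param chirp_rate Linear frequency sweep in Hz/s (sign = direction).
#' @param duration_dist Numeric `(min, max)` seconds, uniform duration bounds.
#' @param call_kind One of `"song"`, `"call"`, `"drum"`.
#' @param group Taxonomic group: `"bird"`, `"insect"` or `"amphibian"`.
#' @param fs Sampling rate the band must respect (`high < fs/2`).
#' @return An object of class `species_template`.
#' @export
species_template <- function(name, carrier_band, n_harmonics = 0, chirp_rate = 0,
                             duration_dist = c(0.1, 0.5),
                             call_kind = c("song", "call", "drum"),
                             group = c("bird", "insect", "amphibian"),
                             fs = 44100) {
  call_kind <- match.arg(call_kind)
  group <- match.arg(group)
  stopifnot(length(carrier_band) == 2, length(duration_dist) == 2)
  if (!(0 < carrier_band[1] && carrier_band[1] < carrier_band[2] &&
        carrier_band[2] < fs / 2)) {
    stop("carrier_band must satisfy 0 < low < high < fs/2")
  }
  if (!(duration_dist[1] > 0 && duration_dist[1] <= duration_dist[2])) {
    stop("duration_dist bounds must be positive and ordered")
  }
  structure(
    list(name = name, carrier_band = as.numeric(carrier_band),
         n_harmonics = as.integer(n_harmonics), chirp_rate = as.numeric(chirp_rate),
         duration_dist = as.numeric(duration_dist), call_kind = call_kind,
         group = group),
    class = "species_template"
  )
}

#' Generate a bank of synthetic species templates
#'
#' Partitions the usable spectrum geometrically into `k` disjoint carrier
#' bands (one per class) and draws per-class harmonics, chirp rates, call
#' kinds and duration bounds. Deterministic given `seed`. Taxonomic groups
#' default to roughly the bird/insect/amphibian proportions of richly
#' annotated field-recording sets; pass `groups = "bird"` for an all-bird
#' bank.
#'
#' @param k Number of classes (>= 2).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param f_min,f_max Spectrum limits for carrier bands; `f_max` defaults to
#'   `0.44 * fs` (just under Nyquist with guard).
#' @param groups Either `NULL` (mixed composition) or a character vector
#'   recycled to length `k`.
#' @param duration_dist Optional `(min, max)` seconds applied to all templates
#'   (otherwise drawn per class).
#' @return List of `k` [species_template] objects with unique names.
#' @export
make_species_bank <- function(k, fs = 44100, seed = 0, f_min = 300,
                              f_max = 0.44 * fs, groups = NULL,
                              duration_dist = NULL) {
  if (k < 2) stop("classification needs >= 2 classes; got k = ", k)
  stopifnot(f_min > 0, f_max > f_min, f_max < fs / 2)
  rng <- rng_stream(seed)

  if (is.null(groups)) {
    n_ins <- round(k * 9 / 61)
    n_amp <- round(k * 1 / 61)
    groups <- c(rep("bird", k - n_ins - n_amp), rep("insect", n_ins),
                rep("amphibian", n_amp))
    groups <- groups[rng$sample_int(k, k)]
  } else {
    groups <- rep_len(groups, k)
  }

  # geometric slot edges, small jittered guard so bands are disjoint
  edges <- exp(seq(log(f_min), log(f_max), length.out = k + 1))
  templates <- vector("list", k)
  for (i in seq_len(k)) {
    lo <- edges[i] * (1 + 0.03 * rng$runif(1))
    hi <- edges[i + 1] * (1 - 0.03 * rng$runif(1))
    nh <- rng$sample_int(3L, 1L) - 1L                  # 0..2
    nh <- min(nh, max(0L, floor(hi / lo) - 1L))        # harmonics fit the band
    width <- hi - lo
    chirp <- rng$runif(1, 0.05, 0.3) * width * sign(rng$runif(1) - 0.5)
    kind <- switch(groups[i],
      bird = rng$sample(c("song", "call", "drum"), 1, prob = c(0.5, 0.45, 0.05)),
      insect = "song",
      amphibian = "call"
    )
    dd <- duration_dist
    if (is.null(dd)) {
      dmin <- rng$runif(1, 0.05, 0.25)
      dd <- c(dmin, dmin + rng$runif(1, 0.1, 0.8))
    }
    templates[[i]] <- species_template(
      name = sprintf("Sp%02d_%s", i, kind),
      carrier_band = c(lo, hi), n_harmonics = nh, chirp_rate = chirp,
      duration_dist = dd, call_kind = kind, group = groups[i], fs = fs
    )
  }
  templates
}

#' Render one call from a template
#'
#' Harmonic stack with linear chirp and a trapezoidal attack/decay envelope;
#' `"drum"` templates render a pulse train carried at the band centre. The
#' instantaneous frequency of every rendered partial stays inside the
#' template's carrier band.
#'
#' @param template A [species_template].
#' @param fs Sampling rate in Hz.
#' @param duration Call length in seconds.
#' @param rng An [rng_stream].
#' @param amplitude Peak amplitude of the rendered call.
#' @return Numeric vector of `round(duration * fs)` samples.
#' @export
render_call <- function(template, fs, duration, rng, amplitude = 1) {
  n <- as.integer(round(duration * fs))
  stopifnot(n >= 2)
  band <- template$carrier_band
  tt <- (seq_len(n) - 1) / fs

  if (template$call_kind == "drum") {
    f0 <- mean(band)
    gate <- abs(sin(pi * 15 * tt))^8 # ~15 pulses/s
    x <- gate * sin(2 * pi * f0 * tt + rng$runif(1, 0, 2 * pi))
  } else {
    nh <- template$n_harmonics
    hi_f0 <- band[2] / (nh + 1)
    if (hi_f0 <= band[1]) { nh <- 0L; hi_f0 <- band[2] }
    sweep <- template$chirp_rate * duration
    # keep f(t) = f0 + sweep * t/duration inside [band_lo, hi_f0]
    lo_s <- band[1] - min(sweep, 0)
    hi_s <- hi_f0 - max(sweep, 0)
    if (lo_s >= hi_s) { sweep <- 0; lo_s <- band[1]; hi_s <- hi_f0 }
    f0 <- rng$runif(1, lo_s, hi_s)
    finst <- f0 + sweep * tt / duration
    phase <- 2 * pi * cumsum(finst) / fs
    x <- numeric(n)
    for (h in seq_len(nh + 1)) {
      x <- x + (1 / h) * sin(h * phase + rng$runif(1, 0, 2 * pi))
    }
  }

  att <- max(2, round(0.15 * n))
  dec <- max(2, round(0.25 * n))
  idx <- seq_len(n)
  env <- pmin(1, idx / att, (n + 1 - idx) / dec)
  x <- x * env
  x * (amplitude / max(abs(x)))
}

#' Specification of a synthetic labeled corpus
#'
#' Defines the statistical shape of a generated soundscape collection:
#' number of classes, class imbalance, file lengths, event overlap rate,
#' background noise level and nuisance tags. Defaults emulate short
#' (1–5 s) field recordings with imbalanced classes, ~20% of events
#' overlapping another species, and white background noise.
#'
#' @param n_species Number of classes.
#' @param files_per_class Either one integer (balanced corpus) or
#'   `(min, max)` bounds of a log-uniform files-per-class draw (imbalance).
#' @param file_len_range `(min, max)` recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param events_per_file Labeled events per recording (1 or 2). Overlap
#'   requires 2.
#' @param overlap_prob Probability that a recording's two events intersect in
#'   time; equals the expected fraction of events overlapping another
#'   species' sound.
#' @param noise_snr_db Per-file signal-to-noise ratio of added Gaussian white
#'   noise, in dB; `Inf` disables noise.
#' @param include_nuisance Emit occasional `"human"`/`"unknown"` events.
#' @param nuisance_prob Per-file probability of a nuisance event.
#' @param bit_depth WAV bit depth, 16 (default) or 32.
#' @param seed Integer seed; the whole corpus is a pure function of the spec.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_species = 10, files_per_class = c(3, 30),
                        file_len_range = c(1, 5), fs = 44100,
                        events_per_file = 2, overlap_prob = 0.2,
                        noise_snr_db = 10, include_nuisance = TRUE,
                        nuisance_prob = 0.1, bit_depth = 16, seed = 0) {
  stopifnot(overlap_prob >= 0, overlap_prob <= 1,
            file_len_range[1] > 0, file_len_range[1] <= file_len_range[2],
            events_per_file %in% c(1L, 2L), bit_depth %in% c(16, 32))
  if (events_per_file == 1 && overlap_prob > 0) {
    stop("overlap requires events_per_file = 2")
  }
  structure(
    list(n_species = as.integer(n_species), files_per_class = files_per_class,
         file_len_range = as.numeric(file_len_range), fs = as.numeric(fs),
         events_per_file = as.integer(events_per_file),
         overlap_prob = overlap_prob, noise_snr_db = noise_snr_db,
         include_nuisance = include_nuisance, nuisance_prob = nuisance_prob,
         bit_depth = bit_depth, seed = as.integer(seed)),
    class = "corpus_spec"
  )
}

# place an event of `dur_s` seconds avoiding `events` (data.frame start/duration);
# returns start in seconds or NA
.place_disjoint <- function(len_s, dur_s, events, rng, tries = 50) {
  for (i in seq_len(tries)) {
    s <- rng$runif(1, 0, len_s - dur_s)
    if (nrow(events) == 0 ||
        all(s + dur_s <= events$start | s >= events$start + events$duration)) {
      return(s)
    }
  }
  NA_real_
}

.draw_duration <- function(template, len_s, rng) {
  for (i in 1:100) {
    d <- rng$runif(1, template$duration_dist[1], template$duration_dist[2])
    if (d < len_s * 0.95) return(d) # never truncate: redraw instead
  }
  len_s * 0.5
}

#' Synthesize one labeled recording
#'
#' Renders a recording of random length inside `spec$file_len_range` with a
#' primary event of class `primary`, optionally a second event of another
#' class (intersecting the first with probability `spec$overlap_prob`),
#' optional nuisance events, and background noise at `spec$noise_snr_db`.
#'
#' @param templates List of [species_template].
#' @param spec A [corpus_spec].
#' @param rng An [rng_stream] carrying the corpus randomness.
#' @param primary Index of the primary event's template (default: random).
#' @return List with `samples` (numeric vector) and `events` (data.frame
#'   `tag`, `start`, `duration`, `group`, `seq_index`, sorted by start).
#' @export
synth_recording <- function(templates, spec, rng, primary = NULL) {
  stopifnot(length(templates) >= 1)
  fs <- spec$fs
  max_hi <- max(vapply(templates, function(t) t$carrier_band[2], 0))
  if (fs <= 2 * max_hi) stop("fs must exceed twice the highest carrier frequency")
  len_s <- rng$runif(1, spec$file_len_range[1], spec$file_len_range[2])
  n <- as.integer(round(len_s * fs))
  if (is.null(primary)) primary <- rng$sample_int(length(templates), 1L)

  ev <- data.frame(tag = character(), start = numeric(), duration = numeric(),
                   group = character(), template = integer(),
                   stringsAsFactors = FALSE)
  add_event <- function(ev, ti, start, dur) {
    tpl <- templates[[ti]]
    rbind(ev, data.frame(tag = tpl$name, start = start, duration = dur,
                         group = tpl$group, template = ti,
                         stringsAsFactors = FALSE))
  }

  d1 <- .draw_duration(templates[[primary]], len_s, rng)
  s1 <- rng$runif(1, 0, len_s - d1)
  ev <- add_event(ev, primary, s1, d1)

  if (spec$events_per_file >= 2 && length(templates) >= 2) {
    others <- setdiff(seq_along(templates), primary)
    ti2 <- if (length(others) == 1) others else rng$sample(others, 1)
    d2 <- .draw_duration(templates[[ti2]], len_s, rng)
    if (rng$runif(1) < spec$overlap_prob) {
      # force intersection with the primary event
      s2 <- rng$runif(1, max(0, s1 - 0.8 * d2), min(len_s - d2, s1 + 0.8 * d1))
      if (!(s2 < s1 + d1 && s1 < s2 + d2)) s2 <- max(0, min(s1, len_s - d2))
    } else {
      s2 <- .place_disjoint(len_s, d2, ev, rng)
      if (is.na(s2)) { d2 <- d2 / 2; s2 <- .place_disjoint(len_s, d2, ev, rng) }
    }
    if (!is.na(s2)) ev <- add_event(ev, ti2, s2, d2)
  }

  nuisance_ev <- NULL
  if (spec$include_nuisance && rng$runif(1) < spec$nuisance_prob) {
    dn <- rng$runif(1, 0.05, min(0.5, len_s / 2))
    sn <- .place_disjoint(len_s, dn, ev, rng)
    if (!is.na(sn)) {
      tag <- rng$sample(c("human", "unknown"), 1)
      nuisance_ev <- data.frame(tag = tag, start = sn, duration = dn,
                                group = "nuisance", template = NA_integer_,
                                stringsAsFactors = FALSE)
    }
  }

  wave <- numeric(n)
  mix_in <- function(wave, x, start_s) {
    i0 <- as.integer(round(start_s * fs))
    idx <- (i0 + 1):(i0 + length(x))
    wave[idx] <- wave[idx] + x
    wave
  }
  for (r in seq_len(nrow(ev))) {
    amp <- rng$runif(1, 0.3, 1)
    x <- render_call(templates[[ev$template[r]]], fs, ev$duration[r], rng, amp)
    wave <- mix_in(wave, x, ev$start[r])
  }
  if (!is.null(nuisance_ev)) {
    nn <- as.integer(round(nuisance_ev$duration * fs))
    burst <- rng$rnorm(nn) * 0.2
    env <- pmin(1, seq_len(nn) / max(2, round(0.1 * nn)),
                (nn + 1 - seq_len(nn)) / max(2, round(0.1 * nn)))
    wave <- mix_in(wave, burst * env, nuisance_ev$start)
    ev <- rbind(ev, nuisance_ev)
  }

  if (is.finite(spec$noise_snr_db)) {
    p_sig <- mean(wave^2)
    if (p_sig > 0) {
      sd_n <- sqrt(p_sig / 10^(spec$noise_snr_db / 10))
      wave <- wave + rng$rnorm(n, sd = sd_n)
    }
  }
  peak <- max(abs(wave))
  if (peak > 0.98) wave <- wave * (0.98 / peak)

  ev <- ev[order(ev$start), , drop = FALSE]
  ev$seq_index <- seq_len(nrow(ev)) - 1L
  rownames(ev) <- NULL
  list(samples = wave, events = ev[, c("tag", "start", "duration", "group", "seq_index")])
}

#' Generate a corpus of labeled synthetic recordings on disk
#'
#' Writes one WAV and one rich-label CSV (`start,duration,tag`) per
#' recording, plus a species metadata table (tag to taxonomic group) and a
#' JSON manifest of every file and event. Fully reproducible from
#' `spec$seed`: the same spec yields byte-identical label tables.
#'
#' @param spec A [corpus_spec].
#' @param out_dir Output directory (created if missing); WAVs under
#'   `audio/`, labels under `labels/`.
#' @param templates Optional pre-built species bank; by default derived
#'   deterministically from the spec.
#' @return The manifest, invisibly a list with `spec`, `species`, `files`,
#'   and `events` entries (also written to `manifest.json`).
#' @export
make_corpus <- function(spec, out_dir, templates = NULL) {
  rng <- rng_stream(derive_seed(spec$seed, 2))
  if (is.null(templates)) {
    templates <- make_species_bank(spec$n_species, spec$fs,
                                   seed = derive_seed(spec$seed, 1))
  }
  audio_dir <- file.path(out_dir, "audio")
  label_dir <- file.path(out_dir, "labels")
  dir.create(audio_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(label_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(audio_dir) || !dir.exists(label_dir)) {
    stop("cannot create output directory: ", out_dir)
  }

  k <- length(templates)
  fpc <- spec$files_per_class
  n_files_class <- if (length(fpc) == 1) {
    rep(as.integer(fpc), k)
  } else {
    # log-uniform imbalance between the bounds
    as.integer(round(exp(rng$runif(k, log(fpc[1]), log(fpc[2])))))
  }

  files <- list()
  events <- list()
  idx <- 0L
  for (ci in seq_len(k)) {
    for (f in seq_len(n_files_class[ci])) {
      idx <- idx + 1L
      rid <- sprintf("rec%04d", idx)
      rec <- synth_recording(templates, spec, rng, primary = ci)
      wav_path <- file.path(audio_dir, paste0(rid, ".wav"))
      write_wav(rec$samples, spec$fs, wav_path, spec$bit_depth)
      lab <- rec$events[, c("start", "duration", "tag")]
      lab$start <- sprintf("%.6f", lab$start)
      lab$duration <- sprintf("%.6f", lab$duration)
      utils::write.csv(lab, file.path(label_dir, paste0(rid, ".csv")),
                       row.names = FALSE, quote = FALSE)
      files[[idx]] <- data.frame(
        recording_id = rid, path = wav_path,
        length_s = length(rec$samples) / spec$fs,
        n_events = nrow(rec$events), primary_tag = templates[[ci]]$name,
        stringsAsFactors = FALSE
      )
      evr <- rec$events
      evr$recording_id <- rid
      events[[idx]] <- evr
    }
  }
  files <- do.call(rbind, files)
  events <- do.call(rbind, events)
  events <- events[, c("recording_id", "seq_index", "tag", "start", "duration", "group")]
  rownames(events) <- NULL

  species <- data.frame(
    tag = vapply(templates, function(t) t$name, ""),
    group = vapply(templates, function(t) t$group, ""),
    call_kind = vapply(templates, function(t) t$call_kind, ""),
    band_lo = vapply(templates, function(t) t$carrier_band[1], 0),
    band_hi = vapply(templates, function(t) t$carrier_band[2], 0),
    stringsAsFactors = FALSE
  )
  utils::write.csv(species[, c("tag", "group")],
                   file.path(out_dir, "species_metadata.csv"),
                   row.names = FALSE, quote = FALSE)

  manifest <- list(spec = unclass(spec), species = species,
                   files = files, events = events,
                   audio_dir = audio_dir, label_dir = label_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
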
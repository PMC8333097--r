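---
title: "Classifying bird calls from raw waveforms: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying bird calls from raw waveforms: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sincbird)
```

## The problem

Passive acoustic monitoring produces long field recordings in which many
species vocalize, often simultaneously, against background noise. Once sound
events have been located and tagged (by an annotator or a detector), the
remaining task is classification: assigning each tagged call to a species
and call type. Classical pipelines first convert audio to spectrogram-like
features, often mel-scaled — a human-hearing-motivated choice whose
suitability for other animals is debatable, and whose selection is a
significant source of engineering effort and bias. `sincbird` implements the
alternative: a network that consumes the raw waveform and learns its own
frequency selectivity.

## The model

A classified item (a cropped call segment, or a call interval inside an
uncut recording) is cut into short frames of `cw_len` = 10 ms, shifted by
`cw_shift` (1 ms at 44.1 kHz by default). Each frame passes through:

1. **A sinc-parameterized band-pass filter bank.** The first convolution's
   kernels are not free parameters; filter $j$ is the ideal band-pass
   kernel
   $$g[n; f_l, f_h] = 2 f_h\,\mathrm{sinc}(2\pi f_h n) - 2 f_l\,\mathrm{sinc}(2\pi f_l n),$$
   with $\mathrm{sinc}(x) = \sin(x)/x$, frequencies normalized by the
   sampling rate and the index $n$ centred on zero, smoothed by a Hamming
   window. Only the two cut-offs $(f_l, f_h)$ per filter are learned —
   2 × 80 = 160 numbers for the default 80 filters of length 251, against
   20 080 for an unconstrained first layer of the same shape. Cut-offs are
   initialized on the mel scale, $\mathrm{mel}(f) = 2595\log_{10}(1+f/700)$,
   as `n_filt + 1` equally spaced mel points between 0 and the Nyquist
   frequency.
2. **A conventional CNN stack:** two further convolutions (60 filters of
   length 5), each convolution followed by max pooling of length 3, layer
   normalization and a leaky ReLU (slope 0.2); the raw frame itself is
   layer-normalized before the first convolution.
3. **A fully-connected stack:** three leaky-ReLU layers of 2048 units with
   batch normalization, then a linear layer and LogSoftmax emitting
   per-frame log-posteriors over the classes.

Training minimizes the frame-level negative log-likelihood (each frame
inherits its item's class) with RMSprop (learning rate 0.001, smoothing
constant 0.95, minibatches of 128 frames). A training frame is drawn from a
uniformly random training item at a uniformly random valid window position,
then multiplied by a random gain from $U(1 - a, 1 + a)$, $a = 0.2$ by
default ("random amplification").

At evaluation time an item is classified by **frame-posterior voting**:
frames are tiled over the item at the configured stride, the exponentiated
log-posteriors are averaged, and the class with the largest mean posterior
wins. Averaging happens in probability space because the vote is defined on
the average posterior; a log-space option exists for comparison.

### The gradient of the sinc layer

With the parameterization above, every kernel tap depends smoothly on the
cut-offs: $\partial g[n]/\partial f_h = (2/f_s)\cos(2\pi f_h n / f_s)$ and
symmetrically (negated) for $f_l$, times the window. The backward pass of
the first layer therefore reduces the full kernel gradient to two numbers
per filter. Because gradient steps may drive raw parameters anywhere,
effective cut-offs are obtained through the total, continuous mapping
$f_l = |p_\mathrm{low}|$, $f_h = \min(f_l + |p_\mathrm{band}|, f_s/2)$
(both clipped to $[0, f_s/2]$), which is surjective onto valid bands and
never produces $f_l > f_h$; its subgradients (sign and clip indicators)
chain through the backward pass. Analytic gradients match central finite
differences to better than $10^{-3}$ relative error in the test suite.

### Numerical choices

* Convolution is computed as cross-correlation over the valid region (no
  padding); sinc kernels are even-symmetric, so the convention is
  observationally identical to convolution, and the impulse-response test
  pins it.
* `sinc(0) = 1` by continuity; equal cut-offs produce the all-zero kernel
  (the two terms cancel identically).
* The Hamming window is the textbook
  $w[m] = 0.54 - 0.46\cos(2\pi m/(I-1))$; no kernel normalization is
  applied beyond the window.
* Ties in the posterior argmax break toward the lowest class index, for
  determinism.
* The 75:25 split gives the train side the floor on fractional counts.
* Mel band edges are clamped exactly to `[f_min, fs/2]` to guard the
  mel-to-Hz round trip against floating-point drift.
* A finite kernel resolves frequencies no finer than roughly $2 f_s / I$
  (the windowed main lobe, ≈ 350 Hz for 251 taps at 44.1 kHz). Mel bands
  narrower than this — the lowest few of an 80-filter bank — have spectra
  that peak at DC rather than inside their nominal band. This is inherent
  to finite FIR kernels, not a defect of the parameterization; tests assert
  exact band containment only above the resolution limit.

## Layers behind the engine

No deep-learning framework is part of the package's dependency set; the
layer engine (im2col convolution, max pooling, layer/batch normalization,
dropout, LogSoftmax and RMSprop) is implemented in vectorized R with
BLAS-backed matrix products and hand-derived backward passes. This keeps
the pipeline self-contained, CPU-friendly at the scaled-down configurations
used throughout, and fully introspectable — the parameter-economy and
architecture-parity claims are checked by walking the layer list.

## What the synthetic generator emulates — and what it does not

The generator stands in for a richly annotated field-recording corpus so
that every downstream stage is testable without external data. It emulates:

* short mono recordings (1–5 s by default) at a configurable rate;
* dozens of imbalanced classes — files per class drawn log-uniformly
  between configurable bounds, mimicking the order-of-magnitude spread of
  real call-type counts;
* per-event rich labels (tag, start, duration) in per-recording CSVs;
* temporal overlap between species: by default each recording carries two
  events which intersect with probability `overlap_prob` (0.2), so the
  event-level overlap fraction matches the configured rate;
* nuisance events tagged `"human"`/`"unknown"`, and Gaussian white
  background noise at a per-file SNR (10 dB default).

Calls are harmonic stacks with a linear chirp and an attack/decay envelope
— band-limited, class-separable signals similar in spirit to tonal bird
syllables. A `"drum"` kind renders a pulse train instead. What the
generator does **not** emulate: natural timbre and syllable structure,
reverberation and distance effects, coloured or non-stationary background
noise, and intra-class variability beyond chirp/duration/fundamental
jitter. A model that separates the synthetic classes has demonstrably
learned frequency-selective structure from raw audio, but synthetic
accuracy says nothing quantitative about accuracy on real field
recordings.

## Class modes and label processing

Rich labels are parsed from per-recording CSVs (`start,duration,tag`).
Nuisance tags are retained but flagged, and excluded from training lists;
events shorter than 10 ms are excluded (unprocessably short at the default
frame). Three class modes mirror common analysis choices: every tag its own
class (`all_classes`); only bird tags (`bird_classes`); call/song/drumming
merged per bird species (`bird_species`). The taxonomic group of a tag is
dataset knowledge and comes from a species metadata table, not from the tag
string. Overlap bookkeeping uses half-open intervals `[start, start+dur)`
so abutting events do not count as overlapping. Cropped segments are
peak-normalized per segment (the common speech-recipe choice); segment
files are named `<recording>_<seq>.wav` by start-time order so tags
re-associate by name alone.

## Problem sizes used in tests and the acceptance script

The package's own checks run on a fixed CPU-scale benchmark chosen as the
smallest configuration that still exercises every stage meaningfully: 5
bird classes with disjoint carrier bands, 40 recordings per class of
0.5–1 s at 16 kHz (one 0.2–0.45 s call each, SNR 10 dB), a model with 16
sinc filters of length 65, two 16 × 5 convolutions and 64-unit
fully-connected layers, trained 10 epochs of 60 minibatches. Three
replicate seeds are averaged; the standard-convolution ablation runs under
the identical budget. The benchmark's evaluation stride is 5 ms (the
stride is configurable; the full-scale default is 1 ms). A separate
20%-overlap corpus supports the overlap-credit analysis.

## Design choices that were genuinely open

* **Pooling:** max pooling of length 3 after every convolution. Without
  pooling the flattened feature dimension is intractable for the
  fully-connected stack; length 3 is the smallest reduction that reaches a
  compact representation in three stages. `pool_len` is configurable so the
  choice is revisitable.
* **Epoch size:** an epoch is `batches_per_epoch` minibatches (default
  800), a bounded, hardware-independent definition; the benchmark uses 60.
* **Normalization placement:** the raw frame is layer-normalized before
  the first convolution as well as after each convolution — standard in
  this architecture family and configurable.
* **Amplitude normalization before vs. after cropping:** per-segment
  (after cropping) is assumed.
* **Overlap credit scope:** a credited prediction may match *any*
  overlapping tag, not only bird tags (both are countable from the same
  bookkeeping).
* **Separate RNG streams** for corpus synthesis, splitting, window
  sampling, amplification and weight initialization, so that an ablation
  (e.g. disabling amplification) perturbs exactly one factor.
* **Minimum bandwidth:** none is imposed beyond $f_h \ge f_l \ge 0$; a
  filter can in principle collapse to zero bandwidth (its kernel is then
  identically zero).

## Known limitations

* The engine is CPU-oriented; full-scale settings (80 × 251 filters,
  2048-unit layers, 44.1 kHz, hundreds of epochs) train only at
  GPU-framework speed and are supported as configuration, not exercised by
  the tests.
* White Gaussian noise is a stand-in: the background spectrum of real
  field recordings is uncharacterized here.
* Batch normalization uses running statistics at evaluation; training with
  batch size 1 is degenerate and unsupported.
* The label-CSV dialect is the package's own (the information content of a
  rich-label release); adapters are needed for other on-disk formats.

## A worked example

```{r example, eval = FALSE}
# generate a small labeled corpus
spec <- corpus_spec(n_species = 4, files_per_class = 10,
                    file_len_range = c(1, 2), fs = 16000,
                    overlap_prob = 0.2, seed = 1)
man <- make_corpus(spec, "corpus")

# parse labels, build a class mode, crop and split
events <- parse_labels("corpus/labels")
groups <- read.csv("corpus/species_metadata.csv")
mode <- class_mode(unique(events$tag[!events$nuisance]), "all_classes", groups)
crop_corpus("corpus/audio", events, "segments")
lists <- build_file_lists(events, mode, split_seed = 7,
                          dialect = "cut", segments_dir = "segments")

# train a scaled-down sinc model and evaluate by posterior voting
model <- build_model(benchmark_net_config("sinc", n_classes = mode$n_classes))
fit <- train(model, load_items(lists$train, "cut"),
             load_items(lists$test, "cut"),
             benchmark_train_config(seed = 7))
report <- evaluate_items(fit$model, load_items(lists$test, "cut"))
report
```

The replicated-run orchestration (`run_experiment()`), history plotting
(`plot_history()`), and the `inst/scripts/sincbird-cli.R` wrapper cover the
same flow as one reproducible unit.
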
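#' Experiment configuration
#'
#' One object tying together corpus, class mode, list dialect, network and
#' training settings, and the replication scheme (several runs differing
#' only in their split seed, sharing one class mapping).
#'
#' @param corpus A [corpus_spec] (the corpus is generated) or a path to an
#'   existing corpus directory with `audio/` and `labels/`.
#' @param net A [net_config]; `n_classes` is overridden by the class mode.
#' @param train A [train_config].
#' @param mode Class mode name (see [class_mode()]).
#' @param dialect File-list dialect, `"cut"` or `"uncut"`.
#' @param n_replicates Number of replicate runs.
#' @param seed Master seed; replicate r splits with `seed + r`.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(corpus = corpus_spec(), net = net_config(),
                              train = train_config(),
                              mode = "all_classes", dialect = "cut",
                              n_replicates = 5, seed = 1) {
  structure(
    list(corpus = corpus, net = net, train = train, mode = mode,
         dialect = dialect, n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "experiment_config"
  )
}

#' Write / read an experiment configuration as YAML
#' @param cfg An [experiment_config].
#' @param path YAML path.
#' @return `write_experiment_config`: `path` invisibly;
#'   `read_experiment_config`: the config.
#' @export
write_experiment_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$corpus <- if (is.character(cfg$corpus)) cfg$corpus else unclass(cfg$corpus)
  x$net <- unclass(cfg$net)
  x$train <- unclass(cfg$train)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.character(x$corpus)) x$corpus <- do.call(corpus_spec, x$corpus)
  x$net$conv_layers <- lapply(x$net$conv_layers, unlist)
  x$net <- do.call(net_config, x$net)
  x$train <- do.call(train_config, x$train)
  do.call(experiment_config, x)
}

#' Run a replicated classification experiment end to end
#'
#' Generates (or loads) the corpus, parses rich labels, crops segments (cut
#' dialect), then for each replicate: builds train/test lists with its own
#' split seed, trains a fresh model, and evaluates file-level metrics. One
#' class mapping is shared across replicates. Per-run histories and metrics
#' plus a mean/SD summary are written under `out_dir` together with a
#' manifest sufficient to rerun the experiment.
#'
#' @param cfg An [experiment_config].
#' @param out_dir Output directory.
#' @param verbose Print epoch progress.
#' @return Manifest list: `config`, `corpus_dir`, `runs` (per-run metrics),
#'   `summary` (data.frame metric / mean / sd), `histories`.
#' @export
run_experiment <- function(cfg, out_dir, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.character(cfg$corpus)) {
    corpus_dir <- cfg$corpus
  } else {
    corpus_dir <- file.path(out_dir, "corpus")
    if (!dir.exists(file.path(corpus_dir, "audio"))) {
      make_corpus(cfg$corpus, corpus_dir)
    }
  }
  audio_dir <- file.path(corpus_dir, "audio")
  label_dir <- file.path(corpus_dir, "labels")
  events <- parse_labels(label_dir)
  species_groups <- utils::read.csv(file.path(corpus_dir, "species_metadata.csv"),
                                    stringsAsFactors = FALSE)
  mode <- class_mode(unique(events$tag[!events$nuisance]), cfg$mode,
                     species_groups)

  segments_dir <- NULL
  if (cfg$dialect == "cut") {
    segments_dir <- file.path(out_dir, "segments")
    if (!dir.exists(segments_dir)) crop_corpus(audio_dir, events, segments_dir)
  }

  net <- cfg$net
  net$n_classes <- mode$n_classes

  runs <- list()
  histories <- list()
  metric_names <- c("accuracy", "roc_auc", "precision", "recall", "f1",
                    "top3", "top5")
  for (r in seq_len(cfg$n_replicates)) {
    run_dir <- file.path(out_dir, sprintf("run_%02d", r))
    dir.create(run_dir, showWarnings = FALSE)
    split_seed <- cfg$seed + r
    lists <- build_file_lists(events, mode, split_seed,
                              dialect = cfg$dialect,
                              segments_dir = segments_dir,
                              audio_dir = audio_dir)
    train_items <- load_items(lists$train, cfg$dialect)
    test_items <- load_items(lists$test, cfg$dialect)

    net_r <- net
    net_r$seed <- derive_seed(cfg$seed, 100 + r)
    model <- build_model(net_r)
    tcfg <- cfg$train
    tcfg$seed <- derive_seed(cfg$seed, 200 + r)
    fit <- train(model, train_items, test_items, tcfg, verbose = verbose)

    report <- evaluate_items(fit$model, test_items)
    utils::write.csv(fit$history, file.path(run_dir, "history.csv"),
                     row.names = FALSE)
    metrics <- lapply(metric_names, function(m) report[[m]])
    names(metrics) <- metric_names
    jsonlite::write_json(metrics, file.path(run_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    save_model(fit$model, file.path(run_dir, "model.rds"))
    runs[[r]] <- list(run = r, split_seed = split_seed, metrics = metrics)
    histories[[r]] <- fit$history
  }

  vals <- sapply(runs, function(x) unlist(x$metrics))
  summary <- data.frame(metric = metric_names,
                        mean = rowMeans(vals),
                        sd = apply(vals, 1L, stats::sd))
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)

  manifest <- list(
    config = list(mode = cfg$mode, dialect = cfg$dialect,
                  n_replicates = cfg$n_replicates, seed = cfg$seed,
                  frontend = cfg$net$frontend),
    corpus_dir = corpus_dir, n_classes = mode$n_classes,
    runs = runs, summary = summary
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  manifest$histories <- histories
  invisible(manifest)
}

#' Plot accuracy-over-epochs curves for replicated runs
#'
#' @param histories List of history data.frames (from [train()] /
#'   [run_experiment()]); rows without a recorded test accuracy are
#'   dropped.
#' @param labels Optional curve labels (default `run 1..n`).
#' @return A ggplot object.
#' @export
plot_history <- function(histories, labels = NULL) {
  if (length(histories) == 0) stop("no histories to plot")
  if (is.data.frame(histories)) histories <- list(histories)
  if (is.null(labels)) labels <- sprintf("run %d", seq_along(histories))
  dfs <- lapply(seq_along(histories), function(i) {
    h <- histories[[i]]
    if (nrow(h) == 0) stop("history ", i, " has no epochs")
    h$run <- labels[i]
    h
  })
  df <- do.call(rbind, dfs)
  df <- df[!is.na(df$test_accuracy), , drop = FALSE]
  if (nrow(df) == 0) stop("no recorded test accuracies in the histories")
  ggplot2::ggplot(df, ggplot2::aes(x = epoch, y = test_accuracy,
                                   colour = run)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "epoch", y = "file-level test accuracy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

# ---- CPU-scale benchmark preset ---------------------------------------------

#' CPU-scale band-separated benchmark
#'
#' A fixed, small study configuration used throughout the package's tests
#' and examples: 5 bird classes with disjoint carrier bands, 40 recordings
#' per class of 0.5-1 s at 16 kHz (one 0.2-0.45 s call each, SNR 10 dB, no
#' overlap), and a scaled-down network (16 first-layer filters of length
#' 65, two 16 x 5 convolutions, 64-unit fully-connected layers) trained for
#' 10 epochs of 60 minibatches. A frame classifier recovering the class
#' structure reaches high file-level accuracy here within minutes on one
#' CPU core (chance is 0.2).
#'
#' @param seed Integer seed (corpus and training derive their streams
#'   from it).
#' @param frontend `"sinc"` or `"standard_conv"`.
#' @return `benchmark_corpus_spec`: a [corpus_spec]; `benchmark_net_config`:
#'   a [net_config]; `benchmark_train_config`: a [train_config].
#' @export
benchmark_corpus_spec <- function(seed = 0) {
  corpus_spec(
    n_species = 5, files_per_class = 40, file_len_range = c(0.5, 1),
    fs = 16000, events_per_file = 1, overlap_prob = 0,
    noise_snr_db = 10, include_nuisance = FALSE, seed = seed
  )
}

#' @rdname benchmark_corpus_spec
#' @export
benchmark_species_bank <- function(seed = 0) {
  make_species_bank(5, fs = 16000, seed = derive_seed(seed, 1),
                    groups = "bird", duration_dist = c(0.2, 0.45))
}

#' @rdname benchmark_corpus_spec
#' @export
benchmark_net_config <- function(frontend = "sinc", seed = 42, n_classes = 5) {
  net_config(
    frontend = frontend, n_filt_1 = 16, len_filt_1 = 65,
    conv_layers = list(c(16, 5), c(16, 5)), pool_len = 3,
    fc_layers = c(64, 64), n_classes = n_classes, fs = 16000,
    cw_len = 10, cw_shift = 5, seed = seed
  )
}

#' @rdname benchmark_corpus_spec
#' @export
benchmark_train_config <- function(seed = 1) {
  train_config(n_epochs = 10, batches_per_epoch = 60, batch_size = 128,
               learning_rate = 0.001, amp_factor = 0.2, eval_every = 5,
               seed = seed)
}

#' Run one benchmark training run end to end
#'
#' Generates the benchmark corpus (cached per directory), crops segments,
#' splits 75:25, trains one model and evaluates it. Used by the package's
#' acceptance checks and the worked example.
#'
#' @param frontend `"sinc"` or `"standard_conv"`.
#' @param seed Seed controlling split, initialization and training streams
#'   (the corpus has its own fixed seed so all runs share one corpus).
#' @param work_dir Scratch directory (corpus and segments are reused if
#'   already present).
#' @param corpus_seed Seed of the shared corpus.
#' @return List with `report` (an `eval_report`), `history`, `model`, and
#'   `lists` (the split).
#' @export
run_benchmark <- function(frontend = "sinc", seed = 1,
                          work_dir = tempfile("sincbird_bench"),
                          corpus_seed = 0) {
  spec <- benchmark_corpus_spec(corpus_seed)
  corpus_dir <- file.path(work_dir, "corpus")
  if (!dir.exists(file.path(corpus_dir, "audio"))) {
    make_corpus(spec, corpus_dir, templates = benchmark_species_bank(corpus_seed))
  }
  events <- parse_labels(file.path(corpus_dir, "labels"))
  species_groups <- utils::read.csv(file.path(corpus_dir, "species_metadata.csv"),
                                    stringsAsFactors = FALSE)
  mode <- class_mode(unique(events$tag[!events$nuisance]), "all_classes",
                     species_groups)
  segments_dir <- file.path(work_dir, "segments")
  if (!dir.exists(segments_dir)) {
    crop_corpus(file.path(corpus_dir, "audio"), events, segments_dir)
  }
  lists <- build_file_lists(events, mode, split_seed = derive_seed(seed, 3),
                            dialect = "cut", segments_dir = segments_dir)
  train_items <- load_items(lists$train, "cut")
  test_items <- load_items(lists$test, "cut")
  model <- build_model(benchmark_net_config(frontend, seed = derive_seed(seed, 4),
                                            n_classes = mode$n_classes))
  fit <- train(model, train_items, test_items,
               benchmark_train_config(seed = derive_seed(seed, 5)))
  report <- evaluate_items(fit$model, test_items)
  list(report = report, history = fit$history, model = fit$model,
       lists = lists, mode = mode, events = events)
}
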
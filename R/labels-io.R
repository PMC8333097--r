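#' Parse rich labels from a directory of per-recording CSV tables
#'
#' Each recording `<id>.wav` has a label table `<id>.csv` with header
#' `start,duration,tag` (times in seconds). Events are returned sorted by
#' `(recording_id, start)` with a 0-based `seq_index` per recording — the
#' same index used as the cropped-segment filename suffix, so tags
#' re-associate with segments by name. Nuisance tags (`"human"`,
#' `"unknown"`) are retained but flagged.
#'
#' @param label_dir Directory of label CSVs.
#' @return data.frame with columns `recording_id`, `tag`, `start`,
#'   `duration`, `seq_index`, `nuisance`.
#' @export
parse_labels <- function(label_dir) {
  files <- sort(list.files(label_dir, pattern = "\\.csv$", full.names = TRUE))
  files <- files[basename(files) != "species_metadata.csv"]
  out <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    tab <- tryCatch(
      utils::read.csv(f, stringsAsFactors = FALSE, colClasses = c(
        start = "numeric", duration = "numeric", tag = "character")),
      error = function(e) stop("malformed label table ", f, ": ", conditionMessage(e))
    )
    if (!all(c("start", "duration", "tag") %in% names(tab))) {
      stop("label table ", f, " lacks start/duration/tag columns")
    }
    if (nrow(tab) == 0) next
    bad <- which(!is.finite(tab$start) | !is.finite(tab$duration) |
                   tab$start < 0 | tab$duration <= 0)
    if (length(bad)) {
      stop("invalid start/duration in ", f, ", row ", bad[1])
    }
    tab <- tab[order(tab$start), , drop = FALSE]
    tab$recording_id <- sub("\\.csv$", "", basename(f))
    tab$seq_index <- seq_len(nrow(tab)) - 1L
    out[[i]] <- tab
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) {
    return(data.frame(recording_id = character(), tag = character(),
                      start = numeric(), duration = numeric(),
                      seq_index = integer(), nuisance = logical(),
                      stringsAsFactors = FALSE))
  }
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$recording_id, ev$start), , drop = FALSE]
  ev$nuisance <- ev$tag %in% c("human", "unknown")
  rownames(ev) <- NULL
  ev[, c("recording_id", "tag", "start", "duration", "seq_index", "nuisance")]
}

#' Segment filename for an event
#'
#' `<recording>_<seq_index>.wav`, zero-padded, so a cropped segment
#' re-associates with its tag purely by name.
#' @param recording_id Recording stem.
#' @param seq_index 0-based event index in start-time order.
#' @return Filename string.
#' @export
segment_filename <- function(recording_id, seq_index) {
  sprintf("%s_%03d.wav", recording_id, seq_index)
}

#' Crop labeled events out of a recording and peak-normalize them
#'
#' Reads a mono recording, cuts out each event's `[start, start + duration)`
#' interval (`round(duration * fs)` samples) and writes it as a new WAV,
#' peak-normalized to unit amplitude. Silent segments are written
#' unnormalized with a warning. An event extending past the end of the
#' audio is an error.
#'
#' @param wav_path Path of the source recording.
#' @param events Events of this recording, as from [parse_labels()].
#' @param out_dir Output directory for segment WAVs.
#' @param bit_depth Output WAV bit depth.
#' @return Character vector of written segment paths (in event order).
#' @export
crop_and_normalize <- function(wav_path, events, out_dir, bit_depth = 16) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- read_wav(wav_path)
  n <- length(w$samples)
  paths <- character(nrow(events))
  for (r in seq_len(nrow(events))) {
    i0 <- as.integer(round(events$start[r] * w$fs))
    len <- as.integer(round(events$duration[r] * w$fs))
    if (i0 + len > n) {
      stop("event ", events$seq_index[r], " of ", wav_path,
           " extends past end of audio")
    }
    seg <- w$samples[(i0 + 1):(i0 + len)]
    peak <- max(abs(seg))
    if (peak == 0) {
      warning("all-zero segment in ", wav_path, " (event ", events$seq_index[r],
              "); written unnormalized")
    } else {
      seg <- seg / peak
    }
    p <- file.path(out_dir, segment_filename(events$recording_id[r],
                                             events$seq_index[r]))
    write_wav(seg, w$fs, p, bit_depth)
    paths[r] <- p
  }
  paths
}

#' Crop every labeled recording of a corpus
#'
#' Convenience wrapper running [crop_and_normalize()] over all recordings
#' referenced by an event table.
#'
#' @param audio_dir Directory holding `<recording_id>.wav` files.
#' @param events Event table from [parse_labels()].
#' @param out_dir Output directory.
#' @param bit_depth Output WAV bit depth.
#' @return data.frame of `recording_id`, `seq_index`, `path`.
#' @export
crop_corpus <- function(audio_dir, events, out_dir, bit_depth = 16) {
  res <- list()
  for (rid in unique(events$recording_id)) {
    ev <- events[events$recording_id == rid, , drop = FALSE]
    paths <- crop_and_normalize(file.path(audio_dir, paste0(rid, ".wav")),
                                ev, out_dir, bit_depth)
    res[[rid]] <- data.frame(recording_id = rid, seq_index = ev$seq_index,
                             path = paths, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Build a tag-to-class-index mapping for one of the three class modes
#'
#' * `all_classes` — every non-nuisance tag is its own class.
#' * `bird_classes` — insect and amphibian tags are dropped; bird tags keep
#'   their call type.
#' * `bird_species` — call, song and drumming tags of one bird species merge
#'   into a single class (the species stem before `"_"`); non-birds dropped.
#'
#' Class indices are dense `0..n_classes-1`, assigned after sorting classes
#' by taxonomic group and then alphabetically.
#'
#' @param tags Character vector of tags in scope (nuisance tags ignored).
#' @param mode One of `"all_classes"`, `"bird_classes"`, `"bird_species"`.
#' @param species_groups data.frame `tag`, `group` mapping each tag to
#'   `"bird"`, `"insect"` or `"amphibian"` (dataset knowledge, not computable
#'   from the tag string).
#' @return Object of class `class_mode`: list with `mode`, `mapping`
#'   (data.frame `tag`, `class`, `class_index`) and `n_classes`.
#' @export
class_mode <- function(tags, mode = c("all_classes", "bird_classes", "bird_species"),
                       species_groups) {
  mode <- match.arg(mode)
  tags <- setdiff(unique(tags), c("human", "unknown"))
  grp <- species_groups$group[match(tags, species_groups$tag)]
  if (anyNA(grp)) {
    stop("no taxonomic group for tag(s): ",
         paste(tags[is.na(grp)], collapse = ", "))
  }
  keep <- if (mode == "all_classes") rep(TRUE, length(tags)) else grp == "bird"
  tags <- tags[keep]
  grp <- grp[keep]
  if (length(tags) == 0) stop("no tags retained under mode ", mode)
  cls <- if (mode == "bird_species") sub("_.*$", "", tags) else tags
  cls_grp <- grp[!duplicated(cls)]
  u <- unique(cls)
  ord <- order(match(cls_grp, c("insect", "amphibian", "bird")), u)
  u <- u[ord]
  mapping <- data.frame(tag = tags, class = cls,
                        class_index = match(cls, u) - 1L,
                        stringsAsFactors = FALSE)
  mapping <- mapping[order(mapping$class_index, mapping$tag), ]
  rownames(mapping) <- NULL
  structure(list(mode = mode, mapping = mapping, classes = u,
                 n_classes = length(u)),
            class = "class_mode")
}

#' Build train/test file lists for a class mode
#'
#' Drops nuisance tags and events shorter than `min_len` (default 10 ms),
#' maps each retained event to its class index, and splits events at random
#' into train and test at `ratio` (train gets the floor). Two list dialects
#' exist: `"cut"` lists cropped-segment paths (`path class`), `"uncut"`
#' lists the original recording with the event's position
#' (`path start_s length_s class`) so the training loader can complete short
#' calls with surrounding audio.
#'
#' @param events Event table from [parse_labels()].
#' @param mode A [class_mode] object.
#' @param split_seed Integer seed of the random split.
#' @param min_len Minimum event duration in seconds (default 0.010).
#' @param dialect `"cut"` or `"uncut"`.
#' @param segments_dir Directory of cropped segments (cut dialect).
#' @param audio_dir Directory of original recordings (uncut dialect).
#' @param ratio Train fraction (default 0.75).
#' @return List with `train` and `test` data.frames (columns `path`,
#'   `start`, `length`, `class_index`, `tag`, `recording_id`, `seq_index`),
#'   the `mode`, and `retained` (all retained events with class indices).
#' @export
build_file_lists <- function(events, mode, split_seed, min_len = 0.010,
                             dialect = c("cut", "uncut"),
                             segments_dir = NULL, audio_dir = NULL,
                             ratio = 0.75) {
  dialect <- match.arg(dialect)
  ev <- events[!events$nuisance, , drop = FALSE]
  ev <- ev[ev$duration >= min_len, , drop = FALSE]
  m <- match(ev$tag, mode$mapping$tag)
  ev <- ev[!is.na(m), , drop = FALSE]
  ev$class_index <- mode$mapping$class_index[m[!is.na(m)]]

  missing_cls <- setdiff(seq_len(mode$n_classes) - 1L, unique(ev$class_index))
  if (length(missing_cls)) {
    stop("class(es) with zero events after filtering: ",
         paste(mode$classes[missing_cls + 1L], collapse = ", "))
  }

  ev$path <- if (dialect == "cut") {
    if (is.null(segments_dir)) stop("cut dialect needs segments_dir")
    file.path(segments_dir, segment_filename(ev$recording_id, ev$seq_index))
  } else {
    if (is.null(audio_dir)) stop("uncut dialect needs audio_dir")
    file.path(audio_dir, paste0(ev$recording_id, ".wav"))
  }

  rng <- rng_stream(split_seed)
  n <- nrow(ev)
  perm <- rng$sample_int(n, n)
  n_train <- floor(ratio * n)
  cols <- c("path", "start", "duration", "class_index", "tag",
            "recording_id", "seq_index")
  tr <- ev[perm[seq_len(n_train)], cols, drop = FALSE]
  te <- ev[perm[setdiff(seq_len(n), seq_len(n_train))], cols, drop = FALSE]
  rownames(tr) <- rownames(te) <- NULL
  list(train = tr, test = te, mode = mode, dialect = dialect,
       ratio = ratio, split_seed = split_seed, retained = ev)
}

#' Write a file list to disk
#'
#' Cut dialect: `path class` per line; uncut dialect:
#' `path start_s length_s class`.
#' @param lst A train or test data.frame from [build_file_lists()].
#' @param path Output file.
#' @param dialect `"cut"` or `"uncut"`.
#' @return `path`, invisibly.
#' @export
write_file_list <- function(lst, path, dialect = c("cut", "uncut")) {
  dialect <- match.arg(dialect)
  lines <- if (dialect == "cut") {
    sprintf("%s %d", lst$path, lst$class_index)
  } else {
    sprintf("%s %.6f %.6f %d", lst$path, lst$start, lst$duration, lst$class_index)
  }
  writeLines(lines, path)
  invisible(path)
}

# events whose half-open interval [start, start+duration) intersects an event
# of a *different tag* in the same recording
.overlap_flags <- function(events) {
  flag <- logical(nrow(events))
  if (nrow(events) == 0) return(flag)
  for (rid in unique(events$recording_id)) {
    i <- which(events$recording_id == rid)
    if (length(i) < 2) next
    s <- events$start[i]; e <- s + events$duration[i]; tg <- events$tag[i]
    for (a in seq_along(i)) {
      flag[i[a]] <- any(s[a] < e & s < e[a] & tg != tg[a])
    }
  }
  flag
}

#' Per-event overlapping-tag sets
#'
#' For each event, the set of *other* tags whose events intersect its
#' `[start, start + duration)` interval in the same recording. Used by
#' [overlap_credit()].
#'
#' @param events Event table from [parse_labels()].
#' @return List (length `nrow(events)`) of character vectors.
#' @export
overlapping_tags <- function(events) {
  out <- vector("list", nrow(events))
  for (rid in unique(events$recording_id)) {
    i <- which(events$recording_id == rid)
    s <- events$start[i]; e <- s + events$duration[i]; tg <- events$tag[i]
    for (a in seq_along(i)) {
      hit <- s[a] < e & s < e[a] & tg != tg[a]
      out[[i[a]]] <- unique(tg[hit])
    }
  }
  out
}

#' Dataset statistics in the style of a rich-label release
#'
#' Per-class event counts and durations, plus corpus totals and the
#' fraction of events overlapping a different tag.
#'
#' @param events Event table from [parse_labels()] (nuisance events are
#'   excluded from per-class rows but counted in `totals$n_events_all`).
#' @param mode Optional [class_mode]; when given, rows are per class of the
#'   mode, otherwise per raw tag.
#' @return List with `per_class` (data.frame `class`, `n_events`,
#'   `n_files`, `total_duration_s`, `mean_duration_s`) and `totals`
#'   (`n_events`, `n_events_all`, `n_files`, `total_duration_s`,
#'   `overlap_fraction`).
#' @export
dataset_stats <- function(events, mode = NULL) {
  ev <- events[!events$nuisance, , drop = FALSE]
  if (!is.null(mode)) {
    m <- match(ev$tag, mode$mapping$tag)
    ev <- ev[!is.na(m), , drop = FALSE]
    ev$class <- mode$mapping$class[m[!is.na(m)]]
  } else {
    ev$class <- ev$tag
  }
  if (nrow(ev) == 0) {
    per_class <- data.frame(class = character(), n_events = integer(),
                            n_files = integer(), total_duration_s = numeric(),
                            mean_duration_s = numeric(), stringsAsFactors = FALSE)
    totals <- list(n_events = 0L, n_events_all = nrow(events), n_files = 0L,
                   total_duration_s = 0, overlap_fraction = NaN)
    return(list(per_class = per_class, totals = totals))
  }
  n_ev <- tapply(ev$duration, ev$class, length)
  cls <- names(n_ev)
  per_class <- data.frame(
    class = cls,
    n_events = as.integer(n_ev),
    n_files = as.integer(tapply(ev$recording_id, ev$class,
                                function(x) length(unique(x)))[cls]),
    total_duration_s = as.numeric(tapply(ev$duration, ev$class, sum)[cls]),
    stringsAsFactors = FALSE
  )
  per_class$mean_duration_s <- per_class$total_duration_s / per_class$n_events
  rownames(per_class) <- NULL
  ov <- .overlap_flags(events[!events$nuisance, , drop = FALSE])
  totals <- list(
    n_events = nrow(ev),
    n_events_all = nrow(events),
    n_files = length(unique(ev$recording_id)),
    total_duration_s = sum(ev$duration),
    overlap_fraction = mean(ov)
  )
  list(per_class = per_class, totals = totals)
}
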
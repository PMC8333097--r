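test_that("parsing an empty label directory yields an empty event table", {
  d <- withr::local_tempdir()
  ev <- parse_labels(d)
  expect_equal(nrow(ev), 0L)
  st <- dataset_stats(ev)
  expect_equal(st$totals$n_events, 0L)
  expect_equal(st$totals$total_duration_s, 0)
})

test_that("malformed label rows fail with file and row named", {
  d <- withr::local_tempdir()
  writeLines(c("start,duration,tag", "0.5,-0.2,SpA_song"),
             file.path(d, "rec1.csv"))
  expect_error(parse_labels(d), "rec1.csv, row 1")
})

test_that("cropping preserves sample counts, normalizes peaks, flags silence", {
  d <- withr::local_tempdir()
  fs <- 44100
  x <- 0.25 * sin(2 * pi * 1000 * (0:(fs - 1)) / fs)
  x[1:2205] <- 0 # leading silence
  wav <- file.path(d, "r.wav")
  write_wav(x, fs, wav)

  events <- data.frame(recording_id = "r", tag = c("SpA_song", "SpA_song"),
                       start = c(0.1, 0), duration = c(0.25, 1),
                       seq_index = 0:1, nuisance = FALSE)
  paths <- crop_and_normalize(wav, events, file.path(d, "seg"))

  s1 <- read_wav(paths[1])
  expect_equal(length(s1$samples), round(0.25 * fs)) # duration x fs samples
  expect_equal(max(abs(s1$samples)), 1, tolerance = 1e-3)

  # full-length event: segment is the normalized full file
  s2 <- read_wav(paths[2])
  expect_equal(length(s2$samples), fs)
  expect_equal(s2$samples, x / max(abs(x)), tolerance = 1e-3)

  # event past end of audio errors
  bad <- data.frame(recording_id = "r", tag = "SpA_song", start = 0.9,
                    duration = 0.5, seq_index = 0L, nuisance = FALSE)
  expect_error(crop_and_normalize(wav, bad, file.path(d, "seg")), "past end")

  # silent event: warned, written unnormalized
  sil <- data.frame(recording_id = "r", tag = "SpA_song", start = 0,
                    duration = 0.04, seq_index = 2L, nuisance = FALSE)
  expect_warning(p <- crop_and_normalize(wav, sil, file.path(d, "seg")),
                 "all-zero")
  expect_equal(max(abs(read_wav(p)$samples)), 0)
})

make_groups <- function(tags) {
  sp <- unique(sub("_.*$", "", tags))
  data.frame(tag = tags,
             group = ifelse(grepl("^Ins", tags), "insect",
                            ifelse(grepl("^Amp", tags), "amphibian", "bird")),
             stringsAsFactors = FALSE)
}

test_that("class modes collapse monotonically and index densely", {
  tags <- c("SpA_song", "SpA_call", "SpB_song", "SpB_drum",
            "Ins1_song", "Ins2_song", "Amp1_call", "human", "unknown")
  sg <- make_groups(tags)

  m_all <- class_mode(tags, "all_classes", sg)
  m_cls <- class_mode(tags, "bird_classes", sg)
  m_sp <- class_mode(tags, "bird_species", sg)

  expect_equal(m_all$n_classes, 7L) # nuisance dropped
  expect_equal(m_cls$n_classes, 4L)
  expect_equal(m_sp$n_classes, 2L)
  expect_true(m_all$n_classes >= m_cls$n_classes)
  expect_true(m_cls$n_classes >= m_sp$n_classes)

  for (m in list(m_all, m_cls, m_sp)) {
    expect_setequal(unique(m$mapping$class_index), 0:(m$n_classes - 1))
  }
  # every bird tag maps under all three modes
  bird_tags <- c("SpA_song", "SpA_call", "SpB_song", "SpB_drum")
  for (m in list(m_all, m_cls, m_sp)) {
    expect_true(all(bird_tags %in% m$mapping$tag))
  }
  # species mode merges call types
  idx <- m_sp$mapping$class_index[m_sp$mapping$tag %in% c("SpA_song", "SpA_call")]
  expect_equal(length(unique(idx)), 1L)
})

test_that("file lists split 75:25, deterministically, with short events removed", {
  tags <- sprintf("Sp%s_song", rep(LETTERS[1:4], each = 25))
  ev <- data.frame(
    recording_id = sprintf("rec%03d", 1:100), tag = tags,
    start = 0, duration = 0.5, seq_index = 0L, nuisance = FALSE
  )
  sg <- make_groups(unique(tags))
  mode <- class_mode(unique(tags), "all_classes", sg)

  l1 <- build_file_lists(ev, mode, split_seed = 5, dialect = "cut",
                         segments_dir = "seg")
  expect_equal(nrow(l1$train), 75L)
  expect_equal(nrow(l1$test), 25L)
  key <- function(df) paste(df$recording_id, df$seq_index)
  expect_length(intersect(key(l1$train), key(l1$test)), 0L)
  expect_setequal(c(key(l1$train), key(l1$test)), key(ev))

  l2 <- build_file_lists(ev, mode, split_seed = 5, dialect = "cut",
                         segments_dir = "seg")
  expect_identical(l1$train, l2$train)

  # sub-10 ms events are excluded from both lists
  ev$duration[7] <- 0.005
  l3 <- build_file_lists(ev, mode, split_seed = 5, dialect = "cut",
                         segments_dir = "seg")
  expect_false(key(ev)[7] %in% c(key(l3$train), key(l3$test)))
  expect_equal(nrow(l3$train) + nrow(l3$test), 99L)

  # a class emptied by filtering is an error naming the class
  ev2 <- ev[!(ev$tag == "SpD_song" & ev$duration >= 0.01), ]
  ev2 <- rbind(ev2, data.frame(recording_id = "recX", tag = "SpD_song",
                               start = 0, duration = 0.004, seq_index = 0L,
                               nuisance = FALSE))
  expect_error(build_file_lists(ev2, mode, 5, dialect = "cut",
                                segments_dir = "seg"), "SpD_song")

  # uncut dialect carries (path, start, length) triples
  lu <- build_file_lists(ev, mode, 5, dialect = "uncut", audio_dir = "aud")
  f <- withr::local_tempfile()
  write_file_list(lu$train, f, "uncut")
  parts <- strsplit(readLines(f)[1], " ")[[1]]
  expect_length(parts, 4L)
})

test_that("dataset statistics are consistent and order-invariant", {
  tc <- tiny_corpus()
  ev <- parse_labels(file.path(tc$dir, "labels"))
  st <- dataset_stats(ev)
  expect_equal(sum(st$per_class$n_events), st$totals$n_events)
  expect_equal(sum(st$per_class$total_duration_s), st$totals$total_duration_s)
  expect_equal(st$per_class$mean_duration_s,
               st$per_class$total_duration_s / st$per_class$n_events)

  perm <- sample(nrow(ev))
  st2 <- dataset_stats(ev[perm, ])
  expect_equal(st2$per_class, st$per_class)
  expect_equal(st2$totals, st$totals)
})

test_that("overlapping tag sets match a direct interval check", {
  ev <- data.frame(
    recording_id = c("a", "a", "a", "b"),
    tag = c("SpA_song", "SpB_song", "SpA_song", "SpB_song"),
    start = c(0, 0.5, 2, 0), duration = c(1, 1, 0.5, 1),
    seq_index = c(0L, 1L, 2L, 0L), nuisance = FALSE
  )
  ov <- overlapping_tags(ev)
  expect_equal(ov[[1]], "SpB_song")
  expect_equal(ov[[2]], "SpA_song")
  expect_length(ov[[3]], 0L)
  expect_length(ov[[4]], 0L)

  # abutting events (half-open intervals) do not overlap
  ev2 <- data.frame(recording_id = "a", tag = c("SpA_song", "SpB_song"),
                    start = c(0, 1), duration = c(1, 1),
                    seq_index = 0:1, nuisance = FALSE)
  expect_length(overlapping_tags(ev2)[[1]], 0L)
})
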
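test_that("stage label mapping merges N3/N4, excludes movement/unknown, rejects garbage", {
  expect_equal(map_stage_labels(c("3", "4")), c(3L, 3L))
  expect_equal(map_stage_labels(c("MOVEMENT", "?")), c(NA_integer_, NA_integer_))
  expect_equal(map_stage_labels(c("W", "1", "2", "R")), c(0L, 1L, 2L, 4L))
  expect_equal(map_stage_labels(c("Sleep stage W", "Sleep stage 4", "Movement time")),
               c(0L, 3L, NA_integer_))
  # idempotent on AASM names
  expect_equal(map_stage_labels(stage_names()), 0:4)
  expect_equal(map_stage_labels(map_stage_labels(stage_names()) |>
                                  (\(v) stage_names()[v + 1])()), 0:4)
  expect_error(map_stage_labels(c("W", "banana")), "banana")
})

test_that("wake-margin trimming keeps 30 min of wake around the sleep period", {
  labels <- c(rep(0L, 100), rep(2L, 50), rep(0L, 100))
  rng <- trim_wake_margin(labels, 60)
  expect_equal(unname(rng), c(41L, 210L))  # [40, 210) zero-based
  expect_equal(unname(trim_wake_margin(rep(2L, 30))), c(1L, 30L))
  expect_equal(unname(trim_wake_margin(c(0L, 0L, 1L, 0L, 0L), 0)), c(3L, 3L))
  expect_warning(rng2 <- trim_wake_margin(rep(0L, 10)), "no sleep")
  expect_equal(unname(rng2), c(1L, 10L))
})

test_that("hypnogram expansion anchors epochs at onsets and drops partial windows", {
  ann <- data.frame(onset = c(0, 90, 150), duration = c(90, 60, 45),
                    text = c("Sleep stage W", "Sleep stage 2", "Sleep stage R"))
  grid <- expand_hypnogram(ann)
  expect_equal(grid$onset, c(0, 30, 60, 90, 120, 150))
  expect_equal(grid$label[4:6], c("Sleep stage 2", "Sleep stage 2", "Sleep stage R"))
})

test_that("segmentation drops excluded epochs, slices contiguously and counts add up", {
  fs <- 100
  n_ep <- 10L
  sig <- seq_len(n_ep * 30 * fs)  # recognisable ramp
  raw <- structure(list(subject_id = "T1", night_id = "T1",
                        channels = list(EEG = sig, EOG = -sig),
                        sampling_rate = fs,
                        annotations = NULL), class = "raw_recording")
  labels <- c(1L, 2L, NA, 2L, 3L, NA, 4L, 2L, 2L, 0L)
  onsets <- 30 * (seq_len(n_ep) - 1)
  rec <- segment_epochs(raw, labels, onsets = onsets, trim = FALSE, zscore = FALSE)
  expect_equal(length(rec$labels), 8L)   # 10 windows, 2 excluded
  expect_equal(rec$labels, labels[!is.na(labels)])
  # epoch k's samples are exactly raw samples [3000k, 3000(k+1))
  k <- rec$index_in_night[2]
  expect_equal(rec$x[2, 1, ], sig[(3000 * (k - 1) + 1):(3000 * k)])
  # no two epochs share samples: all first samples distinct and 3000 apart
  firsts <- rec$x[, 1, 1]
  expect_true(all(diff(sort(firsts)) >= 3000))
})

test_that("segmentation + trimming matches an independent recount of the class histogram", {
  set.seed(99)
  cfg <- generator_config(n_subjects = 1, epochs_per_subject = 200, seed = 31,
                          zscore = FALSE)
  rec <- synth_dataset(cfg)[[1]]
  dirs <- file.path(tempdir(), "edfrt1")
  paths <- write_synth_edf(rec, dirs)
  prep <- prepare_recording(paths["psg"], paths["hypnogram"], zscore = FALSE)
  # recount: expected labels are the generated ones, wake-trimmed
  rng <- trim_wake_margin(rec$labels, 60)
  expected <- rec$labels[rng["first"]:rng["last"]]
  expect_equal(prep$labels, expected)
  expect_equal(table(factor(prep$labels, 0:4)), table(factor(expected, 0:4)))
  unlink(dirs, recursive = TRUE)
})

test_that("EDF pair round-trips signals within 16-bit quantisation and enforces channels", {
  set.seed(5)
  cfg <- generator_config(n_subjects = 1, epochs_per_subject = 10, seed = 12,
                          zscore = FALSE)
  rec <- synth_dataset(cfg)[[1]]
  dirs <- file.path(tempdir(), "edfrt2")
  paths <- write_synth_edf(rec, dirs)

  raw <- load_recording(paths["psg"], paths["hypnogram"])
  expect_equal(names(raw$channels), c("EEG Fpz-Cz", "EOG horizontal"))
  expect_equal(raw$sampling_rate, 100)
  eeg_orig <- as.vector(t(rec$x[, 1, ]))
  # 16-bit quantisation bound: half a step of the physical range
  step <- diff(range(eeg_orig)) / 65535
  expect_lt(max(abs(raw$channels[["EEG Fpz-Cz"]] - eeg_orig)), step)
  # hypnogram annotations reproduce the stage runs
  grid <- expand_hypnogram(raw$annotations)
  expect_equal(map_stage_labels(grid$label), rec$labels)

  expect_error(load_recording(paths["psg"], paths["hypnogram"],
                              channel_names = c("EEG Pz-Oz")),
               "channel not found.*Pz-Oz")
  unlink(dirs, recursive = TRUE)
})

test_that("sampling-rate mismatches are rejected rather than silently resampled", {
  d <- file.path(tempdir(), "edfsr")
  dir.create(d, showWarnings = FALSE)
  psg <- file.path(d, "X1-PSG.edf")
  hyp <- file.path(d, "X1-Hypnogram.edf")
  write_edf(psg, list(`EEG Fpz-Cz` = sin(1:3000)), sampling_rate = 50)
  write_edf(hyp, signals = list(),
            annotations = data.frame(onset = 0, duration = 60,
                                     text = "Sleep stage W"))
  expect_error(load_recording(psg, hyp, channel_names = "EEG Fpz-Cz"),
               "sampling rate mismatch")
  unlink(d, recursive = TRUE)
})

test_that("dataset archive round-trips recordings and writes a manifest", {
  cfg <- generator_config(n_subjects = 2, epochs_per_subject = 12, seed = 3)
  ds <- synth_dataset(cfg)
  d <- file.path(tempdir(), "arch1")
  write_dataset(ds, d)
  expect_true(file.exists(file.path(d, "manifest.json")))
  back <- read_dataset(d)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$x, ds[[1]]$x)
  expect_equal(back[[2]]$labels, ds[[2]]$labels)
  man <- jsonlite::read_json(file.path(d, "manifest.json"), simplifyVector = TRUE)
  expect_equal(man$n_epochs, 24)
  expect_equal(sum(unlist(man$class_histogram)), 24)
  unlink(d, recursive = TRUE)
})

test_that("sleep-edf style file pairing matches by subject-night code", {
  d <- file.path(tempdir(), "pairs")
  dir.create(d, showWarnings = FALSE)
  for (f in c("SC4001E0-PSG.edf", "SC4001EC-Hypnogram.edf",
              "SC4012E0-PSG.edf", "SC4012EC-Hypnogram.edf",
              "SC4999E0-PSG.edf")) file.create(file.path(d, f))
  p <- sleepedf_pairs(d)
  expect_equal(nrow(p), 2)
  expect_equal(p$subject, c("SC4001E0", "SC4012E0"))
  unlink(d, recursive = TRUE)
})
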
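#' Load a PSG / hypnogram file pair
#'
#' Reads the requested channels from an EDF polysomnography file and the
#' stage annotations from its EDF+ hypnogram companion, verifying the
#' sampling rate. No resampling is performed: a channel at a different rate
#' is an error.
#'
#' @param psg_path EDF file with the signals.
#' @param hyp_path EDF+ file with the stage annotations.
#' @param channel_names channels to keep, in modality order (default the
#'   Sleep-EDF convention: EEG Fpz-Cz then EOG horizontal).
#' @param expected_rate required sampling rate in Hz (default 100).
#' @param subject_id,night_id identifiers stored on the result; default
#'   derived from the PSG file name.
#' @return A `raw_recording`: list with `subject_id`, `night_id`,
#'   `channels` (named list of numeric vectors, µV), `sampling_rate` and
#'   `annotations` (data frame `onset`, `duration`, `text` ordered by onset).
#' @export
load_recording <- function(psg_path, hyp_path,
                           channel_names = c("EEG Fpz-Cz", "EOG horizontal"),
                           expected_rate = 100,
                           subject_id = NULL, night_id = NULL) {
  psg <- read_edf(psg_path, channels = channel_names)
  bad <- psg$sampling_rate != expected_rate
  if (any(bad)) {
    stop("sampling rate mismatch for ", paste(channel_names[bad], collapse = ", "),
         ": got ", paste(psg$sampling_rate[bad], collapse = ", "),
         " Hz, expected ", expected_rate, " Hz (no silent resampling)")
  }
  ann <- read_edf(hyp_path)$annotations
  if (is.null(subject_id)) {
    subject_id <- sub("-(PSG|Hypnogram).*$", "", basename(psg_path))
  }
  lens <- vapply(psg$signals, length, integer(1))
  if (length(unique(lens)) > 1) stop("channel lengths differ: ",
                                     paste(lens, collapse = ", "))
  structure(list(subject_id = subject_id,
                 night_id = night_id %||% subject_id,
                 channels = psg$signals,
                 sampling_rate = expected_rate,
                 annotations = ann[order(ann$onset), , drop = FALSE]),
            class = "raw_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expand stage annotations to a per-epoch label grid
#'
#' Turns (onset, duration, stage) annotations into one raw label per 30 s
#' scoring window, anchored at the annotation onsets. Partial trailing
#' windows (duration not a multiple of the epoch length) are dropped.
#'
#' @param annotations data frame with `onset`, `duration`, `text`.
#' @param epoch_s scoring window length in seconds (default 30).
#' @return Data frame with `onset` (s) and `label` (raw stage string), one
#'   row per epoch.
#' @export
expand_hypnogram <- function(annotations, epoch_s = 30) {
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    a <- annotations[i, ]
    n <- if (is.na(a$duration)) 1L else floor(a$duration / epoch_s)
    if (n < 1) return(NULL)
    data.frame(onset = a$onset + epoch_s * (seq_len(n) - 1L),
               label = a$text, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(onset = numeric(0), label = character(0)))
  }
  out[order(out$onset), , drop = FALSE]
}

#' Trim wake margins around the sleep period
#'
#' Restricts a hypnogram to the sleep period plus a fixed wake margin on
#' each side (default 60 epochs = 30 min at 30 s per epoch), the usual
#' Sleep-EDF preprocessing. Operates on mapped stage codes; excluded
#' (`NA`) epochs do not count as sleep.
#'
#' @param labels integer vector of stage codes (0--4, `NA` = excluded).
#' @param margin_epochs wake epochs to keep on each side of the sleep
#'   period (default 60).
#' @return Integer vector `c(first, last)`: the 1-based inclusive index
#'   range to keep. If no sleep epoch exists the full range is returned
#'   with a warning.
#' @export
trim_wake_margin <- function(labels, margin_epochs = 60L) {
  stopifnot(length(labels) > 0, margin_epochs >= 0)
  sleep <- which(!is.na(labels) & labels != 0L)
  if (!length(sleep)) {
    warning("no sleep epochs found; keeping the full recording")
    return(c(first = 1L, last = length(labels)))
  }
  c(first = max(1L, min(sleep) - as.integer(margin_epochs)),
    last = min(length(labels), max(sleep) + as.integer(margin_epochs)))
}

#' Segment a raw recording into labelled 30 s epochs
#'
#' Slices the requested channels into contiguous, non-overlapping 30 s
#' windows anchored at the hypnogram onsets, applies wake-margin trimming,
#' drops excluded (movement / unknown) epochs, and optionally z-scores each
#' epoch per channel.
#'
#' @param raw a `raw_recording` from [load_recording()].
#' @param mapped_labels integer stage codes aligned with `onsets`
#'   (`NA` = excluded).
#' @param onsets epoch onsets in seconds (same length as `mapped_labels`);
#'   default taken from [expand_hypnogram()] on `raw$annotations`.
#' @param epoch_s epoch length in seconds (default 30).
#' @param trim apply [trim_wake_margin()] (default TRUE).
#' @param margin_epochs wake margin passed to [trim_wake_margin()].
#' @param zscore z-score each epoch per channel (default TRUE). Raw µV
#'   scales vary across subjects and channels; per-epoch standardisation
#'   leaves the spectral shape (which carries the stage information) intact.
#' @return A `recording`: list with `subject_id`, `x` (array
#'   `n_epochs x n_channels x samples`), `labels` (integer codes),
#'   `index_in_night` (original epoch indices) and `channels`.
#' @export
segment_epochs <- function(raw, mapped_labels, onsets = NULL, epoch_s = 30,
                           trim = TRUE, margin_epochs = 60L, zscore = TRUE) {
  fs <- raw$sampling_rate
  spe <- as.integer(epoch_s * fs)
  if (is.null(onsets)) {
    grid <- expand_hypnogram(raw$annotations, epoch_s)
    onsets <- grid$onset
  }
  if (length(onsets) != length(mapped_labels)) {
    stop("annotation/label length mismatch: ", length(onsets), " onsets vs ",
         length(mapped_labels), " labels")
  }
  keep <- seq_along(mapped_labels)
  if (trim && length(keep)) {
    rng <- trim_wake_margin(mapped_labels, margin_epochs)
    keep <- seq.int(rng["first"], rng["last"])
  }
  keep <- keep[!is.na(mapped_labels[keep])]
  # drop epochs that would run past the end of the signal
  sig_len <- length(raw$channels[[1]])
  starts <- round(onsets[keep] * fs) + 1L
  ok <- starts + spe - 1L <= sig_len & starts >= 1L
  if (any(!ok)) {
    if (all(!ok)) stop("no epoch fits in the signal (length ", sig_len,
                       ", need ", spe, " samples per epoch)")
    keep <- keep[ok]; starts <- starts[ok]
  }
  n_ch <- length(raw$channels)
  x <- array(NA_real_, c(length(keep), n_ch, spe))
  for (e in seq_along(keep)) {
    for (c in seq_len(n_ch)) {
      seg <- raw$channels[[c]][starts[e]:(starts[e] + spe - 1L)]
      if (zscore) seg <- zscore_epoch(seg)
      x[e, c, ] <- seg
    }
  }
  new_recording(raw$subject_id, x, as.integer(mapped_labels[keep]),
                index_in_night = keep, channels = names(raw$channels))
}

zscore_epoch <- function(v) {
  s <- stats::sd(v)
  (v - mean(v)) / max(s, 1e-8)
}

new_recording <- function(subject_id, x, labels, index_in_night = seq_along(labels),
                          channels = c("EEG", "EOG")) {
  stopifnot(length(dim(x)) == 3, dim(x)[1] == length(labels))
  structure(list(subject_id = subject_id, x = x, labels = labels,
                 index_in_night = as.integer(index_in_night),
                 channels = channels),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  tab <- table(factor(stage_names()[x$labels + 1L], levels = stage_names()))
  cat("<recording> subject", x$subject_id, "-", length(x$labels), "epochs x",
      dim(x$x)[2], "channels x", dim(x$x)[3], "samples\n")
  print(tab)
  invisible(x)
}

#' Extract one epoch from a recording
#'
#' @param rec a `recording`.
#' @param i epoch position.
#' @return List with `eeg`, `eog` (numeric vectors), `label`, `subject_id`
#'   and `index_in_night`.
#' @export
get_epoch <- function(rec, i) {
  list(eeg = rec$x[i, 1, ], eog = rec$x[i, 2, ], label = rec$labels[i],
       subject_id = rec$subject_id, index_in_night = rec$index_in_night[i])
}

#' Full preprocessing chain for one PSG / hypnogram pair
#'
#' [load_recording()] + [map_stage_labels()] + [segment_epochs()] in one
#' call.
#'
#' @inheritParams load_recording
#' @inheritParams segment_epochs
#' @return A `recording`.
#' @export
prepare_recording <- function(psg_path, hyp_path,
                              channel_names = c("EEG Fpz-Cz", "EOG horizontal"),
                              margin_epochs = 60L, zscore = TRUE,
                              subject_id = NULL) {
  raw <- load_recording(psg_path, hyp_path, channel_names,
                        subject_id = subject_id)
  grid <- expand_hypnogram(raw$annotations)
  segment_epochs(raw, map_stage_labels(grid$label), onsets = grid$onset,
                 margin_epochs = margin_epochs, zscore = zscore)
}

#' Pair Sleep-EDF PSG and hypnogram files in a directory
#'
#' Matches `*-PSG.edf` files with their `*-Hypnogram.edf` companions by the
#' subject/night code. Codes match exactly or after dropping their final
#' character, which covers the Sleep-EDF convention where
#' `SC4001E0-PSG.edf` pairs with `SC4001EC-Hypnogram.edf`.
#'
#' @param dir directory to scan.
#' @return Data frame with `subject` (the PSG file's code), `psg` and
#'   `hypnogram` paths.
#' @export
sleepedf_pairs <- function(dir) {
  psg <- sort(list.files(dir, pattern = "-PSG\\.edf$", full.names = TRUE))
  hyp <- sort(list.files(dir, pattern = "-Hypnogram\\.edf$", full.names = TRUE))
  code <- function(p) sub("-(PSG|Hypnogram)\\.edf$", "", basename(p))
  stem <- function(x) substr(x, 1, nchar(x) - 1L)
  hk <- code(hyp)
  rows <- lapply(psg, function(p) {
    k <- code(p)
    m <- which(hk == k)
    if (!length(m)) {
      # Sleep-EDF convention: PSG and hypnogram codes differ only in the
      # final character (e.g. SC4001E0 vs SC4001EC); only accept the
      # stem match when it is unambiguous.
      m <- which(stem(hk) == stem(k))
      if (length(m) != 1L) return(NULL)
    }
    data.frame(subject = k, psg = p, hypnogram = hyp[m[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(subject = character(0), psg = character(0),
                               hypnogram = character(0)) else out
}

#' Write a prepared dataset archive
#'
#' One array file per subject (epochs x channels x samples) plus a label
#' CSV and a JSON manifest with subject ids, the class histogram and the
#' preprocessing flags.
#'
#' @param recordings list of `recording` objects.
#' @param dir output directory (created if needed).
#' @param preprocessing named list recorded verbatim in the manifest.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(recordings, dir, preprocessing = list(zscore = TRUE)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labs <- do.call(rbind, lapply(recordings, function(r) {
    data.frame(subject = r$subject_id, index_in_night = r$index_in_night,
               label = r$labels, stringsAsFactors = FALSE)
  }))
  utils::write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  for (r in recordings) {
    saveRDS(r$x, file.path(dir, paste0(r$subject_id, ".rds")))
  }
  hist <- as.integer(table(factor(labs$label, levels = 0:4)))
  manifest <- list(
    subjects = vapply(recordings, function(r) r$subject_id, character(1)),
    n_epochs = nrow(labs),
    class_histogram = stats::setNames(as.list(hist), stage_names()),
    channels = recordings[[1]]$channels,
    preprocessing = preprocessing
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a prepared dataset archive written by [write_dataset()]
#'
#' @param dir archive directory.
#' @return List of `recording` objects.
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  labs <- utils::read.csv(file.path(dir, "labels.csv"),
                          colClasses = c(subject = "character"))
  lapply(manifest$subjects, function(s) {
    li <- labs[labs$subject == s, ]
    new_recording(s, readRDS(file.path(dir, paste0(s, ".rds"))),
                  as.integer(li$label), index_in_night = li$index_in_night,
                  channels = manifest$channels)
  })
}
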
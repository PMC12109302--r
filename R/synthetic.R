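# Synthetic polysomnography with class-separable spectral structure.
#
# Each stage has a recipe of narrow-band oscillations plus transient events
# (spindles, K-complexes, ocular deflections) per channel; subjects perturb
# the recipes, and hypnograms are generated as geometric runs so stages are
# temporally contiguous like real nights. Spectral *shape*, not amplitude,
# carries the class, so per-epoch z-scoring does not erase the label.

#' Default per-stage signal recipes
#'
#' Textbook stage signatures: W = alpha (8--12 Hz) with fast activity and
#' frequent ocular deflections; N1 = theta (4--7 Hz) with slow rolling eye
#' movements; N2 = theta plus 12--14 Hz spindle bursts and K-complexes;
#' N3 = high-amplitude 0.5--2 Hz delta; REM = low-amplitude mixed theta with
#' large saccadic EOG deflections.
#'
#' Bands are `(center_hz, bandwidth_hz, amplitude_uv)` rows; events are
#' `(kind, rate per 30 s, amplitude_uv)` with kinds `spindle`, `k_complex`,
#' `rem_deflection`.
#'
#' @return Named list of five stage recipes.
#' @export
default_stage_recipes <- function() {
  band <- function(...) matrix(c(...), ncol = 3, byrow = TRUE,
                               dimnames = list(NULL, c("center", "bw", "amp")))
  ev <- function(kind, rate, amp) data.frame(kind = kind, rate = rate, amp = amp,
                                             stringsAsFactors = FALSE)
  list(
    W = list(stage = 0L,
             eeg_bands = band(10, 4, 20, 22, 14, 8),
             eog_bands = band(0.5, 0.4, 8),
             eeg_events = NULL,
             eog_events = ev("rem_deflection", 4, 90),
             noise_sd = 6),
    N1 = list(stage = 1L,
              eeg_bands = band(5.5, 3, 25, 10, 2, 7),
              eog_bands = band(0.35, 0.3, 55),
              eeg_events = NULL,
              eog_events = NULL,
              noise_sd = 6),
    N2 = list(stage = 2L,
              eeg_bands = band(5.5, 3, 22),
              eog_bands = band(0.3, 0.2, 6),
              eeg_events = rbind(ev("spindle", 3, 35), ev("k_complex", 1.2, 90)),
              eog_events = NULL,
              noise_sd = 6),
    N3 = list(stage = 3L,
              eeg_bands = band(1.2, 1.4, 80),
              eog_bands = band(0.3, 0.2, 6),
              eeg_events = NULL,
              eog_events = NULL,
              noise_sd = 6),
    REM = list(stage = 4L,
               eeg_bands = band(5.5, 3, 14, 2.8, 1.2, 9),
               eog_bands = band(0.3, 0.2, 6),
               eeg_events = NULL,
               eog_events = ev("rem_deflection", 8, 130),
               noise_sd = 6)
  )
}

#' Synthetic-dataset configuration
#'
#' @param n_subjects number of subject-nights (default 10).
#' @param epochs_per_subject scoring windows per subject (default 200).
#' @param class_proportions 5-vector of stage proportions (W, N1, N2, N3,
#'   REM) summing to 1; the default is the Sleep-EDF-20 stage mix
#'   (19.6, 6.6, 42.1, 13.5, 18.2 percent).
#' @param subject_jitter relative s.d. applied to recipe amplitudes and
#'   centre frequencies per subject (default 0.1), so recipes differ across
#'   subjects and cross-subject generalisation is non-trivial.
#' @param mean_run_length mean length (epochs) of the geometric stage runs
#'   in the generated hypnograms (default 10).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration.
#' @param zscore z-score each generated epoch per channel (default TRUE,
#'   matching the preprocessing applied to real recordings).
#' @param sampling_rate Hz (default 100); epochs are 30 s.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 10L, epochs_per_subject = 200L,
                             class_proportions = c(0.196, 0.066, 0.421, 0.135, 0.182),
                             subject_jitter = 0.1, mean_run_length = 10,
                             seed = 42L, zscore = TRUE, sampling_rate = 100) {
  stopifnot(length(class_proportions) == 5, all(class_proportions >= 0),
            abs(sum(class_proportions) - 1) < 1e-9,
            n_subjects >= 1, epochs_per_subject >= 1, mean_run_length >= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 epochs_per_subject = as.integer(epochs_per_subject),
                 class_proportions = class_proportions,
                 subject_jitter = subject_jitter,
                 mean_run_length = mean_run_length,
                 seed = as.integer(seed), zscore = zscore,
                 sampling_rate = sampling_rate),
            class = "generator_config")
}

# transient event waveforms, all returning a vector of length n
event_wave <- function(kind, n, fs) {
  t <- seq_len(n) / fs
  dur <- n / fs
  switch(kind,
    spindle = sin(2 * pi * 13 * t) * sin(pi * t / dur)^2,
    k_complex = -sin(2 * pi * t / dur) * sin(pi * t / dur),
    rem_deflection = {
      s <- sin(pi * t / dur)^2
      sample(c(-1, 1), 1) * s
    },
    stop("unknown event kind: ", kind))
}

add_events <- function(x, events, fs) {
  if (is.null(events) || !nrow(events)) return(x)
  n <- length(x)
  for (i in seq_len(nrow(events))) {
    k <- stats::rpois(1, events$rate[i])
    if (k == 0) next
    for (j in seq_len(k)) {
      dur_s <- switch(events$kind[i],
                      spindle = stats::runif(1, 0.5, 1),
                      k_complex = stats::runif(1, 0.8, 1.2),
                      rem_deflection = stats::runif(1, 0.3, 0.7))
      len <- max(8L, round(dur_s * fs))
      start <- sample.int(n - len + 1L, 1)
      x[start:(start + len - 1L)] <- x[start:(start + len - 1L)] +
        events$amp[i] * event_wave(events$kind[i], len, fs)
    }
  }
  x
}

synth_channel <- function(bands, events, noise_sd, n, fs) {
  t <- seq_len(n) / fs
  x <- numeric(n)
  if (!is.null(bands)) {
    for (i in seq_len(nrow(bands))) {
      f <- stats::runif(1, bands[i, "center"] - bands[i, "bw"] / 2,
                        bands[i, "center"] + bands[i, "bw"] / 2)
      x <- x + bands[i, "amp"] * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    }
  }
  x <- add_events(x, events, fs)
  if (noise_sd > 0) x <- x + stats::rnorm(n, sd = noise_sd)
  x
}

#' Generate one synthetic 30 s epoch
#'
#' Draws the EEG and EOG waveforms for one scoring window from a stage
#' recipe: each band contributes a sinusoid at a random frequency and phase,
#' transient events are inserted at Poisson-random onsets, and white noise
#' is added. Uses the R random stream: seed with [set.seed()] for
#' reproducibility.
#'
#' @param stage stage code 0--4; must match `recipe$stage`.
#' @param recipe a stage recipe, see [default_stage_recipes()].
#' @param fs sampling rate in Hz (default 100).
#' @param epoch_s window length in seconds (default 30).
#' @return List with `eeg` and `eog`, numeric vectors of `fs * epoch_s`
#'   samples (µV).
#' @export
synth_epoch <- function(stage, recipe, fs = 100, epoch_s = 30) {
  stopifnot(recipe$stage == stage)
  n <- as.integer(fs * epoch_s)
  list(eeg = synth_channel(recipe$eeg_bands, recipe$eeg_events, recipe$noise_sd, n, fs),
       eog = synth_channel(recipe$eog_bands, recipe$eog_events, recipe$noise_sd, n, fs))
}

# perturb a recipe's amplitudes and centre frequencies for one subject
jitter_recipes <- function(recipes, jitter) {
  lapply(recipes, function(r) {
    for (f in c("eeg_bands", "eog_bands")) {
      b <- r[[f]]
      if (is.null(b)) next
      b[, "amp"] <- b[, "amp"] * pmax(0.2, 1 + stats::rnorm(nrow(b), 0, jitter))
      b[, "center"] <- pmin(45, pmax(0.1, b[, "center"] *
                                       (1 + stats::rnorm(nrow(b), 0, jitter))))
      r[[f]] <- b
    }
    for (f in c("eeg_events", "eog_events")) {
      e <- r[[f]]
      if (is.null(e)) next
      e$amp <- e$amp * pmax(0.2, 1 + stats::rnorm(nrow(e), 0, jitter))
      r[[f]] <- e
    }
    r
  })
}

#' Generate a run-structured hypnogram
#'
#' Stage runs with geometric lengths (mean `mean_run_length`), run stages
#' drawn from `proportions`, so the empirical stage mix converges to the
#' requested proportions while stages stay temporally contiguous.
#'
#' @param n_epochs hypnogram length.
#' @param proportions 5-vector of stage proportions.
#' @param mean_run_length mean run length in epochs.
#' @return Integer vector of stage codes.
#' @export
synth_hypnogram <- function(n_epochs, proportions, mean_run_length = 10) {
  labels <- integer(0)
  while (length(labels) < n_epochs) {
    s <- sample.int(5L, 1, prob = proportions) - 1L
    len <- 1L + stats::rgeom(1, 1 / mean_run_length)
    labels <- c(labels, rep(s, len))
  }
  labels[seq_len(n_epochs)]
}

#' Generate a synthetic multi-subject dataset
#'
#' @param cfg a [generator_config()].
#' @param recipes stage recipes (default [default_stage_recipes()]).
#' @return List of `recording` objects, one per subject (ids `S01`,
#'   `S02`, ...). Deterministic given `cfg$seed`.
#' @export
synth_dataset <- function(cfg = generator_config(), recipes = default_stage_recipes()) {
  fs <- cfg$sampling_rate
  spe <- as.integer(30 * fs)
  lapply(seq_len(cfg$n_subjects), function(s) {
    set.seed(derive_seed(cfg$seed, s))
    rec_s <- jitter_recipes(recipes, cfg$subject_jitter)
    labels <- synth_hypnogram(cfg$epochs_per_subject, cfg$class_proportions,
                              cfg$mean_run_length)
    x <- array(NA_real_, c(cfg$epochs_per_subject, 2L, spe))
    for (e in seq_along(labels)) {
      ep <- synth_epoch(labels[e], rec_s[[labels[e] + 1L]], fs = fs)
      x[e, 1, ] <- if (cfg$zscore) zscore_epoch(ep$eeg) else ep$eeg
      x[e, 2, ] <- if (cfg$zscore) zscore_epoch(ep$eog) else ep$eog
    }
    new_recording(sprintf("S%02d", s), x, labels)
  })
}

#' Export a synthetic recording as an EDF pair
#'
#' Concatenates the epochs into continuous signals and writes a PSG EDF
#' plus an EDF+ hypnogram whose annotations are the stage runs, so the pair
#' can be re-read with [load_recording()] / [prepare_recording()] for
#' round-trip testing. Generate with `zscore = FALSE` to export raw µV.
#'
#' @param rec a `recording`.
#' @param dir output directory.
#' @param fs sampling rate in Hz.
#' @return Named character vector with the `psg` and `hypnogram` paths.
#' @export
write_synth_edf <- function(rec, dir, fs = 100) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  eeg <- as.vector(t(rec$x[, 1, ]))
  eog <- as.vector(t(rec$x[, 2, ]))
  psg <- file.path(dir, paste0(rec$subject_id, "-PSG.edf"))
  hyp <- file.path(dir, paste0(rec$subject_id, "-Hypnogram.edf"))
  write_edf(psg, list(`EEG Fpz-Cz` = eeg, `EOG horizontal` = eog),
            sampling_rate = fs, record_duration = 1)
  runs <- rle(rec$labels)
  ends <- cumsum(runs$lengths)
  ann <- data.frame(onset = 30 * (ends - runs$lengths),
                    duration = 30 * runs$lengths,
                    text = paste("Sleep stage",
                                 c("W", "1", "2", "3", "R")[runs$values + 1L]))
  write_edf(hyp, signals = list(), annotations = ann)
  c(psg = psg, hypnogram = hyp)
}

#' Per-epoch band-power features
#'
#' Relative log band powers of both channels in the five canonical EEG
#' bands (delta 0.5--4, theta 4--8, alpha 8--12, sigma 12--16, beta
#' 16--30 Hz), mainly used to verify that generated data are
#' class-separable with a classical feature set.
#'
#' @param rec a `recording` (or 3-D array epochs x channels x samples).
#' @param fs sampling rate (default 100).
#' @return Matrix `n_epochs x 10` of features.
#' @export
band_power_features <- function(rec, fs = 100) {
  x <- if (is.list(rec)) rec$x else rec
  n <- dim(x)[3]
  freq <- (seq_len(n %/% 2)) * fs / n
  bands <- rbind(c(0.5, 4), c(4, 8), c(8, 12), c(12, 16), c(16, 30))
  sel <- lapply(seq_len(nrow(bands)), function(b)
    which(freq >= bands[b, 1] & freq < bands[b, 2]))
  feats <- matrix(NA_real_, dim(x)[1], 2L * nrow(bands))
  for (e in seq_len(dim(x)[1])) {
    for (c in 1:2) {
      p <- Mod(stats::fft(x[e, c, ]))[2:(n %/% 2 + 1)]^2
      bp <- vapply(sel, function(s) sum(p[s]), numeric(1))
      feats[e, (c - 1) * nrow(bands) + seq_len(nrow(bands))] <-
        log(bp / sum(bp) + 1e-12)
    }
  }
  feats
}
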
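# Minimal EDF / EDF+ support: 16-bit European Data Format signal files and
# EDF+ annotation channels (TALs). Covers what Sleep-EDF style PSG/hypnogram
# pairs need: fixed-rate signals, physical<->digital scaling, and
# onset/duration/text annotations.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: '", x, "'")
  formatC(x, width = -width)
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2)
  if (nchar(s) > width) stop("numeric field does not fit EDF width: ", x)
  edf_pad(s, width)
}

read_ascii <- function(con, n) {
  rawToChar(readBin(con, "raw", n = n))
}

#' Read an EDF or EDF+ file
#'
#' Reads the header, all ordinary signals (scaled to physical units) and any
#' `EDF Annotations` channels (parsed from their time-stamped annotation
#' lists).
#'
#' @param path path to the EDF file.
#' @param channels optional character vector of signal labels to keep; others
#'   are dropped. An error is raised if a requested label is absent.
#' @return List with `signals` (named list of numeric vectors),
#'   `sampling_rate` (named numeric vector, Hz), `annotations` (data frame
#'   with columns `onset`, `duration`, `text`, possibly empty) and `header`
#'   (record count, duration, start date/time strings).
#' @export
read_edf <- function(path, channels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8)                              # version
  read_ascii(con, 80); read_ascii(con, 80)        # patient, recording id
  startdate <- trimws(read_ascii(con, 8))
  starttime <- trimws(read_ascii(con, 8))
  read_ascii(con, 8)                              # header length
  reserved <- trimws(read_ascii(con, 44))
  n_records <- as.integer(trimws(read_ascii(con, 8)))
  record_dur <- as.numeric(trimws(read_ascii(con, 8)))
  ns <- as.integer(trimws(read_ascii(con, 4)))

  field <- function(width) {
    vapply(seq_len(ns), function(i) trimws(read_ascii(con, width)), character(1))
  }
  labels <- field(16)
  field(80)                                       # transducer
  field(8)                                        # physical dimension
  phys_min <- as.numeric(field(8))
  phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8))
  dig_max <- as.numeric(field(8))
  field(80)                                       # prefiltering
  spr <- as.integer(field(8))                     # samples per record
  field(32)                                       # reserved

  is_ann <- labels == "EDF Annotations"
  raw_per_rec <- sum(spr) * 2L
  data <- readBin(con, "raw", n = raw_per_rec * n_records)
  offsets <- c(0L, cumsum(spr * 2L))

  sig_out <- list()
  ann_raw <- raw(0)
  for (i in seq_len(ns)) {
    # byte positions of signal i inside each record
    pos <- as.vector(outer(seq_len(spr[i] * 2L), (seq_len(n_records) - 1L) * raw_per_rec,
                           `+`) + offsets[i])
    bytes <- data[pos]
    if (is_ann[i]) {
      ann_raw <- c(ann_raw, bytes)
    } else {
      dig <- readBin(bytes, "integer", n = spr[i] * n_records, size = 2L,
                     signed = TRUE, endian = "little")
      gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      sig_out[[labels[i]]] <- phys_min[i] + (dig - dig_min[i]) * gain
    }
  }
  rates <- stats::setNames(spr[!is_ann] / record_dur, labels[!is_ann])
  if (any(!is_ann) && (is.na(record_dur) || record_dur <= 0)) {
    stop("invalid EDF record duration: ", record_dur)
  }

  if (!is.null(channels)) {
    missing <- setdiff(channels, names(sig_out))
    if (length(missing)) {
      stop("channel not found: ", paste(missing, collapse = ", "),
           " (available: ", paste(names(sig_out), collapse = ", "), ")")
    }
    sig_out <- sig_out[channels]
    rates <- rates[channels]
  }

  list(signals = sig_out, sampling_rate = rates,
       annotations = parse_tals(ann_raw),
       header = list(n_records = n_records, record_duration = record_dur,
                     startdate = startdate, starttime = starttime,
                     reserved = reserved))
}

# Parse EDF+ time-stamped annotation lists. TALs look like
#   +<onset>[\x15<duration>]\x14<text>\x14[<text>\x14...]\x00
# Record-keeping TALs (empty text) are dropped.
parse_tals <- function(bytes) {
  empty <- data.frame(onset = numeric(0), duration = numeric(0),
                      text = character(0), stringsAsFactors = FALSE)
  if (!length(bytes)) return(empty)
  # NUL bytes only pad/terminate TALs; once removed, TAL boundaries are the
  # "\x14+" transitions (stage texts never start with '+')
  tals <- strsplit(rawToChar(bytes[bytes != as.raw(0)]), "\x14\\+")[[1]]
  if (!length(tals)) return(empty)
  tals[1] <- sub("^\\+", "", tals[1])
  out <- lapply(tals, function(tal) {
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (!length(parts)) return(NULL)
    head <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head[1]))
    if (is.na(onset)) return(NULL)
    duration <- if (length(head) > 1) as.numeric(head[2]) else NA_real_
    texts <- parts[-1]
    texts <- texts[nzchar(texts)]
    if (!length(texts)) return(NULL)
    data.frame(onset = onset, duration = duration, text = texts,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out[order(out$onset), , drop = FALSE]
}

#' Write an EDF / EDF+ file
#'
#' Writes fixed-rate signals as 16-bit EDF records, with an optional EDF+
#' annotation channel carrying (onset, duration, text) entries — enough to
#' emit synthetic PSG/hypnogram pairs that round-trip through [read_edf()].
#'
#' @param path output path.
#' @param signals named list of equal-length numeric vectors, or `NULL` for an
#'   annotations-only file.
#' @param sampling_rate sampling rate in Hz shared by all signals.
#' @param annotations optional data frame with columns `onset`, `duration`,
#'   `text` (seconds, seconds, character).
#' @param record_duration seconds of signal per EDF data record (default 1).
#' @param physical_range length-2 physical min/max used for quantisation; the
#'   default spans the data range. Amplitudes are quantised to 16 bits, so
#'   round-trip error is bounded by half a quantisation step.
#' @return `path`, invisibly.
#' @export
write_edf <- function(path, signals, sampling_rate = 100,
                      annotations = NULL, record_duration = 1,
                      physical_range = NULL) {
  n_sig <- length(signals)
  has_ann <- !is.null(annotations) && nrow(annotations) > 0
  if (n_sig) {
    len <- unique(vapply(signals, length, integer(1)))
    if (length(len) != 1) stop("all signals must have equal length")
    spr_sig <- sampling_rate * record_duration
    if (spr_sig != round(spr_sig)) {
      stop("record_duration * sampling_rate must be an integer")
    }
    spr_sig <- as.integer(spr_sig)
    n_records <- len %/% spr_sig
    if (n_records * spr_sig != len) {
      stop("signal length must be a multiple of samples per record")
    }
  } else {
    n_records <- 1L
  }

  tal_blob <- raw(0)
  if (has_ann) {
    tals <- vapply(seq_len(nrow(annotations)), function(i) {
      a <- annotations[i, ]
      dur <- if (is.na(a$duration)) "" else sprintf("\x15%g", a$duration)
      sprintf("+%g%s\x14%s\x14", a$onset, dur, a$text)
    }, character(1))
    tal_blob <- charToRaw(paste0(tals, collapse = ""))
  }
  # annotation signal: all TALs in record 1, preceded by the record timestamp
  ann_records <- NULL
  if (has_ann || n_sig == 0) {
    stamps <- lapply(seq_len(n_records), function(r) {
      t0 <- (r - 1) * (if (n_sig) record_duration else 1)
      charToRaw(sprintf("+%g\x14\x14", t0))
    })
    rec1 <- c(stamps[[1]], tal_blob)
    spr_ann <- ceiling((length(rec1) + 1L) / 2)  # room for trailing NULs, even bytes
    max_other <- if (n_records > 1) max(vapply(stamps[-1], length, integer(1))) else 0L
    spr_ann <- max(spr_ann, ceiling((max_other + 1L) / 2))
    ann_records <- lapply(seq_len(n_records), function(r) {
      rec <- if (r == 1) rec1 else stamps[[r]]
      c(rec, raw(2L * spr_ann - length(rec)))
    })
  }

  labels <- names(signals)
  if (n_sig && (is.null(labels) || any(!nzchar(labels)))) {
    stop("signals must be a named list")
  }
  dig_min <- -32768; dig_max <- 32767
  ranges <- lapply(seq_len(n_sig), function(i) {
    if (!is.null(physical_range)) return(physical_range)
    r <- range(signals[[i]])
    if (r[1] == r[2]) r <- r + c(-1, 1)
    # pad so that max maps inside the digital range after rounding
    r + c(-1, 1) * diff(r) * 1e-4
  })

  ns <- n_sig + as.integer(!is.null(ann_records))
  header_len <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeBin(charToRaw(edf_pad(x, w)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(header_len, 8)
  wr(if (!is.null(ann_records)) "EDF+C" else "", 44)
  wr(n_records, 8)
  wr(if (n_sig) format(record_duration) else "1", 8)
  wr(ns, 4)

  all_labels <- c(labels, if (!is.null(ann_records)) "EDF Annotations")
  for (l in all_labels) wr(l, 16)
  for (l in all_labels) wr("", 80)
  for (l in all_labels) wr(if (l == "EDF Annotations") "" else "uV", 8)
  for (i in seq_len(ns)) {
    wr(if (i <= n_sig) edf_num(ranges[[i]][1], 8) else "-1", 8)
  }
  for (i in seq_len(ns)) {
    wr(if (i <= n_sig) edf_num(ranges[[i]][2], 8) else "1", 8)
  }
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) {
    wr(if (i <= n_sig) spr_sig else length(ann_records[[1]]) %/% 2L, 8)
  }
  for (i in seq_len(ns)) wr("", 32)

  # re-parse the physical ranges exactly as a reader will see them, so the
  # digital encoding uses the same gain
  hdr_ranges <- lapply(ranges, function(r) {
    as.numeric(c(trimws(edf_num(r[1], 8)), trimws(edf_num(r[2], 8))))
  })
  dig <- lapply(seq_len(n_sig), function(i) {
    r <- hdr_ranges[[i]]
    gain <- (dig_max - dig_min) / (r[2] - r[1])
    d <- round((signals[[i]] - r[1]) * gain + dig_min)
    as.integer(pmin(pmax(d, dig_min), dig_max))
  })
  for (r in seq_len(n_records)) {
    for (i in seq_len(n_sig)) {
      sel <- ((r - 1) * spr_sig + 1):(r * spr_sig)
      writeBin(dig[[i]][sel], con, size = 2L, endian = "little")
    }
    if (!is.null(ann_records)) writeBin(ann_records[[r]], con)
  }
  invisible(path)
}
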
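#' Sleep stage coding
#'
#' The five AASM stages used throughout the package, with fixed integer
#' codes: W = 0, N1 = 1, N2 = 2, N3 = 3, REM = 4. All label vectors in the
#' package are integer vectors on this coding; `stage_names()` gives the
#' canonical printable order.
#'
#' @return `stage_names()` returns the character vector
#'   `c("W", "N1", "N2", "N3", "REM")`; `n_stages()` returns 5L.
#' @export
stage_names <- function() c("W", "N1", "N2", "N3", "REM")

#' @rdname stage_names
#' @export
n_stages <- function() 5L

#' Map raw R&K hypnogram labels to AASM stage codes
#'
#' Applies the standard Sleep-EDF relabelling: R&K stages 3 and 4 are merged
#' into AASM N3, stage R becomes REM, and MOVEMENT / UNKNOWN epochs are
#' excluded (returned as `NA`). Both bare tokens (`"W"`, `"1"`, `"R"`, ...)
#' and the verbose EDF+ annotation texts (`"Sleep stage 1"`,
#' `"Movement time"`) are accepted.
#'
#' @param raw_labels character vector of raw stage strings.
#' @return Integer vector of the same length with stage codes 0--4;
#'   excluded epochs (movement / unknown) are `NA_integer_`.
#' @examples
#' map_stage_labels(c("3", "4"))           # both map to N3 (code 3)
#' map_stage_labels(c("MOVEMENT", "?"))    # both excluded (NA)
#' @export
map_stage_labels <- function(raw_labels) {
  stopifnot(is.character(raw_labels))
  x <- toupper(trimws(raw_labels))
  x <- sub("^SLEEP STAGE ", "", x)
  x[x == "MOVEMENT TIME"] <- "M"
  lut <- c(
    "W" = 0L, "1" = 1L, "2" = 2L, "3" = 3L, "4" = 3L, "R" = 4L,
    "N1" = 1L, "N2" = 2L, "N3" = 3L, "N4" = 3L, "REM" = 4L
  )
  excluded <- c("M", "MOVEMENT", "?", "UNKNOWN")
  out <- rep(NA_integer_, length(x))
  known <- x %in% names(lut)
  out[known] <- lut[x[known]]
  bad <- !known & !(x %in% excluded)
  if (any(bad)) {
    stop("unrecognized stage label(s): ",
         paste(unique(raw_labels[bad]), collapse = ", "))
  }
  out
}
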
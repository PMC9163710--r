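#' Construct a sampled time series
#'
#' Basic container used throughout the package: a regularly sampled numeric
#' vector with its sampling rate and labelling metadata.
#'
#' @param values Numeric vector of samples. Must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Channel label, e.g. `"O2Hb_L"` or `"ABP"`.
#' @param units Unit string, e.g. `"umol/L"` or `"mmHg"`.
#' @return An object of class `nirs_ts`.
#' @export
time_series <- function(values, fs, label = "", units = "") {
  if (!is.numeric(values) || length(values) == 0L) {
    stop("`values` must be a non-empty numeric vector", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("`values` must be finite (resolve missing samples before ingestion)",
         call. = FALSE)
  }
  structure(
    list(values = as.numeric(values), fs = fs,
         label = as.character(label), units = as.character(units)),
    class = "nirs_ts"
  )
}

#' @export
print.nirs_ts <- function(x, ...) {
  cat(sprintf("<nirs_ts> %s [%s]: %d samples @ %g Hz (%.1f s)\n",
              x$label, x$units, length(x$values), x$fs,
              length(x$values) / x$fs))
  invisible(x)
}

#' @export
length.nirs_ts <- function(x) length(x$values)

#' Duration of a time series in seconds
#' @param x A `nirs_ts`.
#' @return Duration in seconds.
#' @export
ts_duration <- function(x) length(x$values) / x$fs

#' Time axis of a series (seconds, starting at 0)
#' @param x A `nirs_ts`.
#' @return Numeric vector of sample times.
#' @export
ts_time <- function(x) (seq_along(x$values) - 1) / x$fs

# Channel set every recording must provide, with nominal rates.
.recording_channels <- c("O2Hb_L", "HHb_L", "O2Hb_R", "HHb_R", "ABP")

#' Construct a multi-channel recording
#'
#' A recording bundles the two-channel prefrontal NIRS concentration series
#' (oxy- and deoxyhemoglobin, left and right) with the continuous arterial
#' blood pressure series of one subject. Channels may have different sampling
#' rates (NIRS typically 20 Hz, ABP 1000 Hz) but must span the same duration
#' to within one sample period of the slowest channel.
#'
#' @param channels Named list of [time_series()] objects. Names must include
#'   `O2Hb_L`, `HHb_L`, `O2Hb_R`, `HHb_R`, `ABP`.
#' @param subject_id Subject identifier.
#' @param check_span If `TRUE` (default), require all channels to span a
#'   common duration within one sample period of the slowest channel.
#' @return An object of class `nirs_recording`.
#' @export
recording <- function(channels, subject_id = "subject", check_span = TRUE) {
  if (!is.list(channels) || is.null(names(channels))) {
    stop("`channels` must be a named list of time series", call. = FALSE)
  }
  missing_ch <- setdiff(.recording_channels, names(channels))
  if (length(missing_ch) > 0L) {
    stop("missing required channel(s): ", paste(missing_ch, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(channels)) {
    if (!inherits(channels[[nm]], "nirs_ts")) {
      stop("channel `", nm, "` is not a time_series", call. = FALSE)
    }
  }
  durs <- vapply(channels, ts_duration, numeric(1))
  if (check_span) {
    slowest <- min(vapply(channels, function(ch) ch$fs, numeric(1)))
    if (diff(range(durs)) > 1 / slowest + 1e-9) {
      stop("channels span different durations (", paste(round(durs, 3), collapse = ", "),
           " s); call align() first", call. = FALSE)
    }
  }
  structure(
    list(channels = channels, subject_id = subject_id,
         duration = min(durs)),
    class = "nirs_recording"
  )
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("<nirs_recording> subject %s, %.1f s\n", x$subject_id, x$duration))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-7s %8d samples @ %6g Hz\n", nm, length(ch$values), ch$fs))
  }
  invisible(x)
}

# Unwrap a wrapped phase sequence (inverse of modulo-2*pi reduction).
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1], p[1] + cumsum(d))
}
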
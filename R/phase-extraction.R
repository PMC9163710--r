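#' Frequency band definition
#'
#' @param name Band name.
#' @param f_lo,f_hi Band edges in Hz, `0 < f_lo < f_hi`.
#' @return An object of class `nirs_band`.
#' @export
band <- function(name, f_lo, f_hi) {
  if (!(is.numeric(f_lo) && is.numeric(f_hi) && f_lo > 0 && f_hi > f_lo)) {
    stop("need 0 < f_lo < f_hi", call. = FALSE)
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "nirs_band")
}

#' Canonical analysis bands
#'
#' The very-low-frequency and low-frequency hemodynamic bands used for the
#' oxyhemoglobin oscillations, and the cardiac band used for the arterial
#' blood pressure oscillation.
#'
#' @return A named list of [band()] objects: `VLF` (0.02-0.07 Hz),
#'   `LF` (0.07-0.2 Hz), `CARDIAC` (0.6-2 Hz).
#' @export
canonical_bands <- function() {
  list(
    VLF = band("VLF", 0.02, 0.07),
    LF = band("LF", 0.07, 0.2),
    CARDIAC = band("CARDIAC", 0.6, 2.0)
  )
}

#' Continuous wavelet transform with the complex Morlet wavelet
#'
#' Computes wavelet coefficients of a series over a logarithmic frequency
#' grid covering one band, using the complex Morlet mother wavelet
#' `psi(u) = pi^(-1/4) exp(-i 2 pi u) exp(-u^2 / 2)` with scale-to-frequency
#' map `f = 1/s` and L2 (`1/sqrt(s)`) normalization. The transform is
#' evaluated in the frequency domain: at scale `s` the wavelet acts as a
#' Gaussian band-pass centered on `f = 1/s` that passes positive frequencies
#' only, so the coefficient argument is an instantaneous phase that increases
#' with time for a physical oscillation. A cone-of-influence margin of
#' `sqrt(2) * s` seconds per scale marks edge-contaminated coefficients.
#'
#' @param series A [time_series()]. Must last at least `3 / f_lo` seconds.
#' @param band A [band()].
#' @param voices_per_octave Frequency-grid density (default 16, minimum 8).
#' @return A `wavelet_field`: list with complex `coefficients`
#'   (frequency x time), `freqs` (Hz, increasing), `coi` (seconds per
#'   frequency), `fs`, and `band`.
#' @export
morlet_cwt <- function(series, band, voices_per_octave = 16) {
  stopifnot(inherits(series, "nirs_ts"), inherits(band, "nirs_band"))
  if (voices_per_octave < 8) {
    stop("`voices_per_octave` must be at least 8", call. = FALSE)
  }
  dur <- ts_duration(series)
  if (dur < 3 / band$f_lo) {
    stop("series too short: need at least ", round(3 / band$f_lo, 1),
         " s (3 periods of ", band$f_lo, " Hz), have ", round(dur, 1), " s",
         call. = FALSE)
  }
  pre <- .cwt_prepare(series, band, voices_per_octave)
  coef <- matrix(0 + 0i, nrow = length(pre$freqs), ncol = pre$n)
  for (j in seq_along(pre$freqs)) {
    W <- stats::fft(pre$X * .morlet_weight(1 / pre$freqs[j], pre$fgrid),
                    inverse = TRUE) / pre$nfft
    coef[j, ] <- W[seq_len(pre$n)]
  }
  structure(
    list(coefficients = coef, freqs = pre$freqs, coi = sqrt(2) / pre$freqs,
         fs = series$fs, band = band),
    class = "wavelet_field"
  )
}

# Frequency grid, padded FFT, and FFT frequency axis shared by the full
# transform and the band-averaged fast path.
.cwt_prepare <- function(series, band, voices_per_octave) {
  n_oct <- log2(band$f_hi / band$f_lo)
  k <- 0:floor(n_oct * voices_per_octave + 1e-9)
  freqs <- band$f_lo * 2^(k / voices_per_octave)
  if (freqs[length(freqs)] < band$f_hi * (1 - 1e-9)) {
    freqs <- c(freqs, band$f_hi)
  }
  x <- series$values - mean(series$values)
  n <- length(x)
  # pad past the slowest wavelet's effective support to curb wrap-around
  pad <- ceiling(4 * series$fs / band$f_lo)
  nfft <- stats::nextn(n + 2 * pad, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  fgrid <- c(0:(nfft %/% 2), -((nfft - 1) %/% 2):-1) / nfft * series$fs
  list(freqs = freqs, X = X, fgrid = fgrid, n = n, nfft = nfft)
}

# Continuous-FT weight of the scaled Morlet wavelet; zero at f <= 0.
.morlet_weight <- function(s, fgrid) {
  sqrt(2 * pi * s) * pi^(-1 / 4) * exp(-2 * pi^2 * (s * fgrid - 1)^2)
}

#' Band phase directly from a series
#'
#' Fast path equivalent to `band_phase(morlet_cwt(series, band, ...))`: the
#' band-averaged complex coefficient is linear in the per-scale wavelet
#' weights, so it is computed with a single FFT pair using the mean weight
#' over the frequency grid. Numerically identical to the two-step route.
#'
#' @param series A [time_series()].
#' @param band A [band()].
#' @param voices_per_octave Frequency-grid density (default 16).
#' @param min_cycles Minimum valid-span length in cycles of `f_lo`.
#' @return A `phase_series` (see [band_phase()]).
#' @export
extract_band_phase <- function(series, band, voices_per_octave = 16,
                               min_cycles = 5) {
  stopifnot(inherits(series, "nirs_ts"), inherits(band, "nirs_band"))
  if (voices_per_octave < 8) {
    stop("`voices_per_octave` must be at least 8", call. = FALSE)
  }
  dur <- ts_duration(series)
  if (dur < 3 / band$f_lo) {
    stop("series too short: need at least ", round(3 / band$f_lo, 1),
         " s (3 periods of ", band$f_lo, " Hz), have ", round(dur, 1), " s",
         call. = FALSE)
  }
  pre <- .cwt_prepare(series, band, voices_per_octave)
  Hmean <- rowMeans(vapply(pre$freqs,
                           function(f) .morlet_weight(1 / f, pre$fgrid),
                           numeric(length(pre$fgrid))))
  avg <- (stats::fft(pre$X * Hmean, inverse = TRUE) / pre$nfft)[seq_len(pre$n)]
  .phase_from_avg(avg, series$fs, band, min_cycles)
}

# Shared construction of a phase_series from the band-averaged coefficient.
.phase_from_avg <- function(avg, fs, band, min_cycles) {
  phase <- unwrap_phase(Arg(avg))
  n <- length(phase)
  dur <- n / fs
  margin <- sqrt(2) / band$f_lo
  t0 <- margin
  t1 <- dur - margin
  if (t1 - t0 < min_cycles / band$f_lo) {
    stop("valid span after cone-of-influence trimming (",
         round(max(t1 - t0, 0), 1), " s) is shorter than ", min_cycles,
         " cycles of ", band$f_lo, " Hz", call. = FALSE)
  }
  tt <- (seq_len(n) - 1) / fs
  structure(
    list(phase = phase, fs = fs, band = band,
         valid_span = c(t0, t1),
         valid_idx = which(tt >= t0 & tt <= t1)),
    class = "phase_series"
  )
}

#' Band phase from a wavelet field
#'
#' Averages the complex wavelet coefficients across the band's frequency
#' grid at each time point and takes the argument of the average, unwrapped
#' over time: the band is treated as a single oscillatory mode whose phase
#' is dominated by the locally strongest scales. Samples inside the
#' cone-of-influence margin at the band's lowest frequency are excluded from
#' the valid span.
#'
#' @param field A `wavelet_field` from [morlet_cwt()].
#' @param min_cycles Minimum number of cycles of `f_lo` the valid span must
#'   cover (default 5).
#' @return A `phase_series`: list with `phase` (radians, unwrapped, full
#'   record length), `fs`, `band`, `valid_span` (start/end seconds after
#'   cone trimming), and `valid_idx` (sample indices inside the span).
#' @export
band_phase <- function(field, min_cycles = 5) {
  stopifnot(inherits(field, "wavelet_field"))
  avg <- colMeans(field$coefficients)
  .phase_from_avg(avg, field$fs, field$band, min_cycles)
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> band %s [%g, %g] Hz, %d samples @ %g Hz, valid [%.1f, %.1f] s\n",
              x$band$name, x$band$f_lo, x$band$f_hi, length(x$phase), x$fs,
              x$valid_span[1], x$valid_span[2]))
  invisible(x)
}

#' Intersection of valid spans of several phase series
#'
#' @param phases List of `phase_series` with a common sampling rate.
#' @return Numeric `c(start, end)` in seconds.
#' @export
common_valid_span <- function(phases) {
  if (length(phases) == 0L) stop("empty phase set", call. = FALSE)
  fs <- unique(vapply(phases, function(p) p$fs, numeric(1)))
  if (length(fs) != 1L) {
    stop("phase series have different sampling rates", call. = FALSE)
  }
  t0 <- max(vapply(phases, function(p) p$valid_span[1], numeric(1)))
  t1 <- min(vapply(phases, function(p) p$valid_span[2], numeric(1)))
  if (t1 <= t0) {
    stop("insufficient overlap: valid spans do not intersect", call. = FALSE)
  }
  c(t0, t1)
}

# Extract the phase samples of `p` inside a time span (seconds).
phase_in_span <- function(p, span) {
  tt <- (seq_along(p$phase) - 1) / p$fs
  p$phase[tt >= span[1] & tt <= span[2]]
}
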
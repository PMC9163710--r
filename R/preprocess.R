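#' Centered moving average
#'
#' Smooths a series with a centered box filter, the standard first pass for
#' suppressing noise-like single-sample spikes in NIRS concentration series.
#' The window is rounded to the nearest odd sample count; edges use shrinking
#' (one-sided) windows so no data are invented at the boundaries.
#'
#' @param series A [time_series()].
#' @param window Window width in seconds (default 5 s). Must be at least two
#'   sample periods and no longer than the series.
#' @return A smoothed `nirs_ts` of identical length and rate.
#' @export
moving_average <- function(series, window = 5) {
  stopifnot(inherits(series, "nirs_ts"))
  n <- length(series$values)
  if (window < 2 / series$fs) {
    stop("`window` must be at least two sample periods", call. = FALSE)
  }
  if (window > n / series$fs) {
    stop("`window` is longer than the series", call. = FALSE)
  }
  w <- round(window * series$fs)
  if (w %% 2 == 0) w <- w + 1
  h <- (w - 1) / 2
  x <- series$values
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  out <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  time_series(out, series$fs, series$label, series$units)
}

# Rolling standard deviation with shrinking edge windows (centered).
rolling_sd <- function(x, w) {
  n <- length(x)
  h <- (w - 1) %/% 2
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  m <- hi - lo + 1
  mu <- (cs[hi + 1] - cs[lo]) / m
  v <- (cs2[hi + 1] - cs2[lo]) / m - mu^2
  v[v < 0] <- 0
  sqrt(v * m / pmax(m - 1, 1))
}

#' Cubic-spline motion-artifact correction
#'
#' Detects motion-contaminated segments as stretches where the moving
#' standard deviation exceeds a multiple of the series' robust scale (MAD),
#' models each contaminated segment with a cubic smoothing spline, subtracts
#' the spline trend, and re-levels the segment with a linear ramp joining the
#' clean neighborhoods on either side. Samples outside flagged segments are
#' returned unchanged, so the correction is strictly local.
#'
#' @param series A [time_series()] (nominally a 20 Hz NIRS channel).
#' @param detection_window Moving-SD window in seconds (default 2, min 1).
#' @param threshold_sd Flagging threshold as a multiple of the robust scale
#'   (default 4).
#' @param spar Smoothing parameter passed to [stats::smooth.spline()]
#'   (default 0.5; lower follows the artifact more closely).
#' @param pad Seconds added on each side of a flagged stretch so the whole
#'   artifact support is corrected (default half the detection window).
#' @return Corrected `nirs_ts`. The number of corrected segments is attached
#'   as attribute `"n_segments"`.
#' @export
spline_motion_correct <- function(series, detection_window = 2,
                                  threshold_sd = 4, spar = 0.5,
                                  pad = detection_window / 2) {
  stopifnot(inherits(series, "nirs_ts"))
  if (detection_window < 1) {
    stop("`detection_window` must be at least 1 s", call. = FALSE)
  }
  x <- series$values
  n <- length(x)
  w <- max(3L, round(detection_window * series$fs))
  if (w %% 2 == 0) w <- w + 1L
  rs <- rolling_sd(x, w)
  robust <- stats::mad(x)
  if (robust == 0) robust <- stats::sd(x)
  flagged <- rs > threshold_sd * robust
  if (!any(flagged)) {
    out <- series
    attr(out, "n_segments") <- 0L
    return(out)
  }
  if (all(flagged)) {
    stop("artifact saturation: every sample flagged; raise `threshold_sd`",
         call. = FALSE)
  }
  # expand each flagged run by `pad` seconds and merge overlapping runs
  np <- round(pad * series$fs)
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- cbind(pmax(starts[r$values] - np, 1L), pmin(ends[r$values] + np, n))
  if (nrow(seg) > 1L) {
    merged <- seg[1, , drop = FALSE]
    for (k in 2:nrow(seg)) {
      if (seg[k, 1] <= merged[nrow(merged), 2] + 1L) {
        merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], seg[k, 2])
      } else {
        merged <- rbind(merged, seg[k, ])
      }
    }
    seg <- merged
  }
  out <- x
  tt <- ts_time(series)
  edge <- max(2L, round(series$fs))  # 1 s neighborhoods for re-leveling
  fit_trend <- function(idx) {
    if (length(idx) >= 8L) {
      fit <- stats::smooth.spline(tt[idx], x[idx], spar = spar)
      stats::predict(fit, tt[idx])$y
    } else {
      rep(mean(x[idx]), length(idx))
    }
  }
  for (k in seq_len(nrow(seg))) {
    i0 <- seg[k, 1]; i1 <- seg[k, 2]
    idx <- i0:i1
    # a smoothing spline cannot follow an abrupt onset, so split the segment
    # at large sample-to-sample jumps and model each smooth piece separately
    jumps <- which(abs(diff(x[idx])) > threshold_sd * robust)
    bounds <- unique(c(0L, jumps, length(idx)))
    trend <- numeric(length(idx))
    for (p in seq_len(length(bounds) - 1L)) {
      piece <- (bounds[p] + 1L):bounds[p + 1L]
      trend[piece] <- fit_trend(idx[piece])
    }
    resid <- x[idx] - trend
    left <- if (i0 > 1) mean(x[max(1, i0 - edge):(i0 - 1)]) else NA_real_
    right <- if (i1 < n) mean(x[(i1 + 1):min(n, i1 + edge)]) else NA_real_
    if (is.na(left)) left <- right
    if (is.na(right)) right <- left
    if (is.na(left)) left <- right <- mean(x[idx])
    ramp <- seq(left, right, length.out = length(idx))
    out[idx] <- resid + ramp
  }
  res <- time_series(out, series$fs, series$label, series$units)
  attr(res, "n_segments") <- nrow(seg)
  res
}

# Kaiser-window FIR lowpass design for a given transition band and stopband
# attenuation (dB), following the standard Kaiser order/beta formulas.
design_kaiser_lowpass <- function(fs, f_pass, f_stop, atten_db = 65) {
  delta_w <- 2 * pi * (f_stop - f_pass) / fs
  beta <- if (atten_db > 50) {
    0.1102 * (atten_db - 8.7)
  } else if (atten_db >= 21) {
    0.5842 * (atten_db - 21)^0.4 + 0.07886 * (atten_db - 21)
  } else 0
  n <- ceiling((atten_db - 7.95) / (2.285 * delta_w))
  if (n %% 2 == 1) n <- n + 1  # even order -> odd-length symmetric FIR
  fc <- (f_pass + f_stop) / 2
  b <- signal::fir1(n, fc / (fs / 2), type = "low",
                    window = signal::kaiser(n + 1, beta))
  b / sum(b)  # unit DC gain
}

# Zero-phase FIR filtering with optional decimation: reflect-pad, convolve,
# remove the linear-phase group delay, keep every q-th sample. Only the kept
# output samples are ever computed (polyphase evaluation), so decimation by
# large factors costs ~ n_out * length(b) operations.
fir_filter_zerophase <- function(x, b, q = 1L) {
  nb <- length(b)
  gd <- (nb - 1) / 2  # linear-phase FIR group delay (samples)
  npad <- nb
  n <- length(x)
  if (n <= npad + 1) {
    stop("series too short (", n, " samples) for a length-", nb,
         " anti-aliasing filter", call. = FALSE)
  }
  xp <- c(2 * x[1] - rev(x[2:(npad + 1)]),
          x,
          2 * x[n] - rev(x[(n - npad):(n - 1)]))
  # conv[k] = sum_j b[j] * xp[k - j + 1]; output i aligns with conv[npad+gd+i]
  pos <- seq.int(npad + gd + 1, npad + gd + n, by = q)
  y <- numeric(length(pos))
  for (j in seq_len(nb)) {
    y <- y + b[j] * xp[pos - j + 1]
  }
  y
}

#' Anti-aliased downsampling
#'
#' Low-pass filters with a zero-phase Kaiser-window FIR (stopband at the new
#' Nyquist frequency, >= 60 dB attenuation) and decimates by the integer rate
#' ratio. Large factors are decomposed into stages (factors of at most 10) so
#' filter lengths stay moderate; this is the standard way to take a 1000 Hz
#' ABP series to the 20 Hz NIRS time base.
#'
#' @param series A [time_series()].
#' @param target_rate Target sampling rate in Hz. The source rate must be an
#'   integer multiple.
#' @param atten_db Minimum stopband attenuation in dB (default 65).
#' @return Decimated `nirs_ts` at `target_rate`.
#' @export
downsample <- function(series, target_rate, atten_db = 65) {
  stopifnot(inherits(series, "nirs_ts"))
  ratio <- series$fs / target_rate
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("source rate (", series$fs, " Hz) is not an integer multiple of ",
         target_rate, " Hz", call. = FALSE)
  }
  q <- as.integer(round(ratio))
  if (q == 1L) return(series)
  # stage plan: peel factors <= 10, largest first
  stages <- integer(0)
  rem <- q
  for (f in c(10L, 8L, 7L, 6L, 5L, 4L, 3L, 2L)) {
    while (rem %% f == 0L && rem > 10L) {
      stages <- c(stages, f)
      rem <- rem %/% f
    }
  }
  stages <- c(stages, rem)
  x <- series$values
  fs <- series$fs
  f_pass_final <- 0.8 * target_rate / 2
  for (s in stages) {
    new_fs <- fs / s
    b <- design_kaiser_lowpass(fs, f_pass = f_pass_final,
                               f_stop = new_fs / 2, atten_db = atten_db)
    x <- fir_filter_zerophase(x, b, q = s)
    fs <- new_fs
  }
  time_series(x, target_rate, series$label, series$units)
}

#' Trim channels of a recording to their common time span
#'
#' All channels are assumed to share a nominal common start; each is trimmed
#' to the maximal duration covered by every channel. Applied after
#' downsampling, this leaves all channels at a common rate and equal length.
#'
#' @param rec A [recording()] (constructed with `check_span = FALSE` if the
#'   channels differ in length).
#' @param min_overlap Minimum acceptable common span in seconds (default 600).
#' @return An aligned `nirs_recording`.
#' @export
align <- function(rec, min_overlap = 600) {
  stopifnot(inherits(rec, "nirs_recording"))
  durs <- vapply(rec$channels, ts_duration, numeric(1))
  common <- min(durs)
  if (common < min_overlap) {
    stop("insufficient overlap: common span ", round(common, 1),
         " s is below the ", min_overlap, " s minimum", call. = FALSE)
  }
  channels <- lapply(rec$channels, function(ch) {
    keep <- floor(common * ch$fs + 1e-9)
    if (keep < length(ch$values)) {
      time_series(ch$values[seq_len(keep)], ch$fs, ch$label, ch$units)
    } else ch
  })
  recording(channels, rec$subject_id, check_span = FALSE)
}
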
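#' Tissue oxygenation index series
#'
#' Pointwise TOI = 100 * O2Hb / (O2Hb + HHb), the fraction of oxygenated
#' hemoglobin in total hemoglobin, in percent. Requires absolute-equivalent
#' concentration series (a device-exported or synthetic baseline plus
#' fluctuations): the ratio is undefined for pure zero-mean change signals,
#' and any sample with a non-positive total-hemoglobin denominator is
#' rejected.
#'
#' @param o2hb,hhb [time_series()] objects of equal length and rate, in the
#'   same concentration units.
#' @return A `nirs_ts` of TOI values in percent.
#' @export
toi_series <- function(o2hb, hhb) {
  stopifnot(inherits(o2hb, "nirs_ts"), inherits(hhb, "nirs_ts"))
  if (length(o2hb$values) != length(hhb$values) || o2hb$fs != hhb$fs) {
    stop("`o2hb` and `hhb` must have equal length and sampling rate",
         call. = FALSE)
  }
  total <- o2hb$values + hhb$values
  bad <- which(total <= 0)
  if (length(bad) > 0L) {
    stop("degenerate input: non-positive total hemoglobin at sample ", bad[1],
         " (TOI requires absolute-equivalent concentrations)", call. = FALSE)
  }
  time_series(100 * o2hb$values / total, o2hb$fs, "TOI", "%")
}

#' Per-subject TOI summary
#'
#' Time means of the left and right prefrontal TOI series over the analyzed
#' span, plus their bilateral average (mean TOI).
#'
#' @param toi_left,toi_right TOI series from [toi_series()].
#' @return A list with `ltoi`, `rtoi`, and `mean_toi`, each in percent.
#' @export
summarize_toi <- function(toi_left, toi_right) {
  stopifnot(inherits(toi_left, "nirs_ts"), inherits(toi_right, "nirs_ts"))
  if (length(toi_left$values) == 0L || length(toi_right$values) == 0L) {
    stop("empty TOI series", call. = FALSE)
  }
  ltoi <- mean(toi_left$values)
  rtoi <- mean(toi_right$values)
  list(ltoi = ltoi, rtoi = rtoi, mean_toi = (ltoi + rtoi) / 2)
}
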
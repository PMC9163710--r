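#' Write a recording to delimited text files
#'
#' Writes three files per subject into `dir`: `<id>_nirs_L.csv` (columns
#' `time`, `O2Hb_L`, `HHb_L`), `<id>_nirs_R.csv`, and `<id>_abp.csv`
#' (`time`, `ABP`). Time is in seconds from 0.
#'
#' @param rec A [recording()].
#' @param dir Output directory (created if missing).
#' @param digits Significant digits to keep (default 6).
#' @return Invisibly, the written file paths.
#' @export
write_recording <- function(rec, dir, digits = 6) {
  stopifnot(inherits(rec, "nirs_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- rec$subject_id
  sig <- function(x) signif(x, digits)
  paths <- character(3)
  for (k in 1:2) {
    side <- c("L", "R")[k]
    o2 <- rec$channels[[paste0("O2Hb_", side)]]
    hb <- rec$channels[[paste0("HHb_", side)]]
    df <- data.frame(time = ts_time(o2), o2 = sig(o2$values),
                     hb = sig(hb$values))
    names(df) <- c("time", paste0("O2Hb_", side), paste0("HHb_", side))
    paths[k] <- file.path(dir, sprintf("%s_nirs_%s.csv", id, side))
    data.table::fwrite(df, paths[k])
  }
  abp <- rec$channels$ABP
  df <- data.frame(time = ts_time(abp), ABP = sig(abp$values))
  paths[3] <- file.path(dir, sprintf("%s_abp.csv", id))
  data.table::fwrite(df, paths[3])
  invisible(paths)
}

# Read one delimited signal file; validate time column and infer the rate.
read_signal_file <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  if (ncol(df) < 2 || names(df)[1] != "time") {
    stop("format error in ", path, ": first column must be `time` (seconds)",
         call. = FALSE)
  }
  tm <- df$time
  dt <- diff(tm)
  bad <- which(dt <= 0)
  if (length(bad) > 0) {
    stop("format error in ", path, ": time not strictly increasing at line ",
         bad[1] + 2, call. = FALSE)
  }
  med <- stats::median(dt)
  jit <- which(abs(dt - med) > 0.01 * med)
  if (length(jit) > 0) {
    stop("format error in ", path, ": sampling-interval jitter above 1% at line ",
         jit[1] + 2, call. = FALSE)
  }
  fs <- 1 / med
  # snap to the nominal rate when the written time stamps round-trip through
  # decimal text (e.g. 19.999999999999996 -> 20)
  if (abs(fs - round(fs)) < 1e-6 * fs) fs <- round(fs)
  lapply(names(df)[-1], function(nm) time_series(df[[nm]], fs, nm))
}

#' Read a recording from delimited text files
#'
#' Reads the per-subject signal files written by [write_recording()] (or any
#' delimited files with a header row and a strictly increasing `time` first
#' column, seconds). Channel labels are validated against the required set;
#' the sampling rate is inferred from the median time step and checked for
#' uniformity to 1%.
#'
#' @param signal_paths Character vector of file paths jointly providing the
#'   channels `O2Hb_L`, `HHb_L`, `O2Hb_R`, `HHb_R`, `ABP`.
#' @param subject_id Subject identifier.
#' @return A [recording()].
#' @export
read_recording <- function(signal_paths, subject_id = "subject") {
  channels <- list()
  for (p in signal_paths) {
    for (ts in read_signal_file(p)) {
      if (!ts$label %in% .recording_channels) {
        stop("format error in ", p, ": unknown channel `", ts$label, "`",
             call. = FALSE)
      }
      channels[[ts$label]] <- ts
    }
  }
  recording(channels, subject_id)
}

#' Read cohort metadata
#'
#' @param path CSV with at least `subject_id`, `group`, `moca` columns.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  req <- c("subject_id", "group", "moca")
  if (!all(req %in% names(df))) {
    stop("metadata must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis with their documented
#' defaults. The returned list round-trips losslessly through JSON.
#'
#' @param ... Named overrides of any default.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    bands = list(vlf = c(0.02, 0.07), lf = c(0.07, 0.2), cardiac = c(0.6, 2.0)),
    ma_window = 5,              # s, NIRS moving average
    spline_window = 2,          # s, motion-artifact detection window
    spline_threshold = 4,       # robust scales
    target_rate = 20,           # Hz, common time base
    min_overlap = 600,          # s, minimum common span
    voices_per_octave = 16,
    K = 2,                      # Fourier basis order
    window_vlf = 400,           # s, inference window (VLF pairing)
    window_lf = 200,            # s, inference window (LF pairing)
    prop_const = 0.2,           # information diffusion
    tol = 1e-6,                 # inference convergence tolerance
    family_alpha = 0.05,
    n_boot = 2000,
    seed = 1,
    input_dir = NULL,
    output_dir = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}
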
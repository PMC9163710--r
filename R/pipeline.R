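#' Process one subject: preprocessing, TOI, phases, coupling metrics
#'
#' Runs the per-subject stages in their documented order: cubic-spline
#' motion-artifact correction of the NIRS channels, TOI from the corrected
#' (unsmoothed) series, 5-s moving-average smoothing of the NIRS channels,
#' anti-aliased downsampling of ABP to the common time base, alignment,
#' Morlet-wavelet phase extraction (cardiac band from ABP, VLF and LF from
#' each O2Hb channel), and windowed dynamical Bayesian inference of the
#' cardiac-to-oxyhemoglobin coupling for each channel/band pairing.
#'
#' @param rec A [recording()].
#' @param config A [pipeline_config()].
#' @return One-row data frame of subject metrics: TOI triple plus `cs_*` and
#'   `cd_*` per channel/band.
#' @export
process_subject <- function(rec, config = pipeline_config()) {
  stopifnot(inherits(rec, "nirs_recording"))
  ch <- rec$channels
  # motion-artifact correction on the NIRS concentration channels
  nirs_names <- c("O2Hb_L", "HHb_L", "O2Hb_R", "HHb_R")
  for (nm in nirs_names) {
    ch[[nm]] <- spline_motion_correct(ch[[nm]], config$spline_window,
                                      config$spline_threshold)
  }
  # TOI on corrected, unsmoothed series
  toi <- summarize_toi(toi_series(ch$O2Hb_L, ch$HHb_L),
                       toi_series(ch$O2Hb_R, ch$HHb_R))
  # spike suppression for the oscillation analysis
  for (nm in nirs_names) ch[[nm]] <- moving_average(ch[[nm]], config$ma_window)
  if (ch$ABP$fs != config$target_rate) {
    ch$ABP <- downsample(ch$ABP, config$target_rate)
  }
  rec2 <- align(recording(ch, rec$subject_id, check_span = FALSE),
                min_overlap = config$min_overlap)
  ch <- rec2$channels

  bands <- list(
    vlf = band("VLF", config$bands$vlf[1], config$bands$vlf[2]),
    lf = band("LF", config$bands$lf[1], config$bands$lf[2]),
    cardiac = band("CARDIAC", config$bands$cardiac[1], config$bands$cardiac[2])
  )
  vpo <- config$voices_per_octave
  phi_card <- extract_band_phase(ch$ABP, bands$cardiac, vpo)
  basis <- build_basis(config$K)
  out <- data.frame(subject_id = rec$subject_id,
                    ltoi = toi$ltoi, rtoi = toi$rtoi, mean_toi = toi$mean_toi,
                    stringsAsFactors = FALSE)
  for (side in c("L", "R")) {
    o2 <- ch[[paste0("O2Hb_", side)]]
    for (bn in c("vlf", "lf")) {
      phi_slow <- extract_band_phase(o2, bands[[bn]], vpo)
      win <- if (bn == "vlf") config$window_vlf else config$window_lf
      met <- subject_coupling(phi_card, phi_slow, basis, window = win,
                              prop_const = config$prop_const,
                              tol = config$tol)
      pfc <- if (side == "L") "lpfc" else "rpfc"
      out[[paste0("cs_", pfc, "_", bn)]] <- met$cs_ao
      out[[paste0("cd_", pfc, "_", bn)]] <- met$cd
    }
  }
  out
}

#' Run the full pipeline over a cohort
#'
#' Per-subject processing ([process_subject()]) followed by the cohort
#' statistics stage ([group_report()]) when at least three groups are
#' present. A subject whose processing fails (e.g. a valid span too short
#' for phase extraction) is excluded with a warning, not fatally.
#'
#' @param config A [pipeline_config()]. When `cohort` is `NULL`, recordings
#'   are read from `config$input_dir` (files as written by
#'   [write_recording()], plus `metadata.csv`).
#' @param cohort Optional in-memory cohort from [simulate_cohort()].
#' @return List with `metrics` (subject-metrics data frame), `report` (a
#'   [group_report()] or `NULL`), and `excluded` (named character vector of
#'   failure messages).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  if (is.null(cohort)) {
    if (is.null(config$input_dir)) {
      stop("either `cohort` or `config$input_dir` must be given", call. = FALSE)
    }
    meta <- read_metadata(file.path(config$input_dir, "metadata.csv"))
    recs <- lapply(meta$subject_id, function(sid) {
      paths <- file.path(config$input_dir,
                         sprintf("%s_%s.csv", sid, c("nirs_L", "nirs_R", "abp")))
      read_recording(paths, sid)
    })
    names(recs) <- meta$subject_id
  } else {
    meta <- cohort$metadata
    recs <- lapply(cohort$subjects, `[[`, "recording")
    names(recs) <- meta$subject_id
  }
  rows <- list()
  excluded <- character(0)
  for (sid in names(recs)) {
    res <- tryCatch(process_subject(recs[[sid]], config),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      warning("subject ", sid, " excluded: ", res, call. = FALSE)
      excluded[sid] <- res
    } else {
      rows[[sid]] <- res
    }
  }
  if (length(rows) == 0) stop("no subject processed successfully", call. = FALSE)
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  keep <- match(metrics$subject_id, meta$subject_id)
  metrics$group <- meta$group[keep]
  metrics$moca <- meta$moca[keep]
  report <- NULL
  if (length(unique(metrics$group)) >= 3L &&
      all(table(metrics$group) >= 3L)) {
    report <- group_report(metrics, family_alpha = config$family_alpha,
                           n_boot = config$n_boot, seed = config$seed)
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(metrics, file.path(config$output_dir, "subject_metrics.csv"))
    if (!is.null(report)) {
      jsonlite::write_json(
        report_to_list(report),
        file.path(config$output_dir, "group_report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
    }
    manifest <- list(config = unclass(config), n_subjects = nrow(metrics),
                     excluded = as.list(excluded))
    jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null", pretty = TRUE)
  }
  list(metrics = metrics, report = report, excluded = excluded)
}

# Flatten a group_report into plain lists for JSON serialization.
report_to_list <- function(report) {
  list(
    family_alpha = report$family_alpha,
    variables = lapply(report$variables, function(v) {
      if (is.character(v$anova)) return(list(error = v$anova))
      checks <- if (is.character(v$checks)) {
        list(ks_p = list(error = v$checks), levene_p = NA_real_)
      } else {
        list(ks_p = as.list(v$checks$ks), levene_p = v$checks$levene_p)
      }
      c(checks,
        list(anova_f = v$anova$anova_f, anova_p = v$anova$anova_p,
             corrected_alpha = v$anova$corrected_alpha,
             pairwise = v$anova$pairwise))
    }),
    correlations = report$correlations,
    roc = report$roc
  )
}
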
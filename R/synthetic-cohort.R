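#' Phase-oscillator specification
#'
#' Describes one oscillatory mode of the generative model: a stochastic
#' phase oscillator with a fixed natural frequency, white dynamical phase
#' noise, and a waveform amplitude used when the phase is rendered into a
#' measured signal.
#'
#' @param natural_frequency Natural frequency in Hz (> 0).
#' @param phase_noise_intensity Intensity of the Gaussian white phase noise
#'   in rad^2/s (variance accumulated per second; >= 0).
#' @param amplitude Waveform amplitude in signal units (>= 0).
#' @param amplitude_jitter_sd Fractional jitter of the rendered amplitude
#'   (>= 0).
#' @return An `oscillator_spec`.
#' @export
oscillator_spec <- function(natural_frequency, phase_noise_intensity = 0,
                            amplitude = 1, amplitude_jitter_sd = 0) {
  if (natural_frequency <= 0) stop("natural_frequency must be > 0", call. = FALSE)
  if (phase_noise_intensity < 0 || amplitude < 0 || amplitude_jitter_sd < 0) {
    stop("noise intensity, amplitude, and jitter must be >= 0", call. = FALSE)
  }
  structure(list(natural_frequency = natural_frequency,
                 phase_noise_intensity = phase_noise_intensity,
                 amplitude = amplitude,
                 amplitude_jitter_sd = amplitude_jitter_sd),
            class = "oscillator_spec")
}

#' Coupling specification between two oscillators
#'
#' The coupling function added to the driven oscillator's phase equation,
#' expressed in the same Fourier basis the inference uses:
#' `q(phi_src, phi_dst) = sum value * trig(a * phi_src + b * phi_dst)`.
#'
#' @param direction Character vector of length 2: source and target
#'   oscillator identifiers.
#' @param coefficients Data frame with columns `a`, `b`, `trig`
#'   (`"sin"`/`"cos"`), `value` (rad/s). Every `(a, b)` must satisfy
#'   `(a, b) != (0, 0)`.
#' @param k_max Maximum admissible harmonic index (default 5).
#' @return A `coupling_spec`.
#' @export
coupling_spec <- function(direction, coefficients, k_max = 5) {
  stopifnot(is.character(direction), length(direction) == 2L)
  req <- c("a", "b", "trig", "value")
  if (!is.data.frame(coefficients) || !all(req %in% names(coefficients))) {
    stop("`coefficients` must have columns a, b, trig, value", call. = FALSE)
  }
  if (any(coefficients$a == 0 & coefficients$b == 0)) {
    stop("(a, b) = (0, 0) is not a coupling term", call. = FALSE)
  }
  if (any(abs(coefficients$a) > k_max | abs(coefficients$b) > k_max)) {
    stop("harmonic index exceeds k_max = ", k_max, call. = FALSE)
  }
  structure(list(direction = direction, coefficients = coefficients),
            class = "coupling_spec")
}

# Scale all coupling coefficients by a factor.
scale_coupling <- function(coupling, factor) {
  coupling$coefficients$value <- coupling$coefficients$value * factor
  coupling
}

# True directed coupling strength implied by a coupling_spec: Euclidean norm
# of all coefficients whose term depends on the source phase (a != 0).
true_coupling_strength <- function(coupling) {
  cf <- coupling$coefficients
  sqrt(sum(cf$value[cf$a != 0]^2))
}

# Evaluate a coupling_spec at phase samples.
eval_coupling <- function(coupling, phi_src, phi_dst) {
  cf <- coupling$coefficients
  q <- 0
  for (k in seq_len(nrow(cf))) {
    arg <- cf$a[k] * phi_src + cf$b[k] * phi_dst
    q <- q + cf$value[k] * (if (cf$trig[k] == "sin") sin(arg) else cos(arg))
  }
  q
}

#' Group profile for the synthetic cohort
#'
#' Group-level effect sizes: how strongly the cardiac ABP oscillation drives
#' the slow oxyhemoglobin oscillations (per band), the tissue-oxygenation
#' level, and the cognitive-score distribution. Defaults encode the expected
#' clinical pattern: impaired groups have higher coupling (poorer
#' autoregulatory damping) and lower TOI.
#'
#' @param group_name One of `"NC"`, `"MCI"`, `"CI"`.
#' @param coupling_scale_vlf,coupling_scale_lf Dimensionless multipliers on
#'   the base coupling coefficients (>= 0).
#' @param toi_mean,toi_sd TOI draw distribution, percent (`toi_mean` in
#'   [0, 100]).
#' @param moca_mean,moca_sd MoCA score draw distribution, points
#'   (`moca_mean` in [0, 30]).
#' @return A `group_profile`.
#' @export
group_profile <- function(group_name, coupling_scale_vlf, coupling_scale_lf,
                          toi_mean, toi_sd, moca_mean, moca_sd) {
  if (!group_name %in% c("NC", "MCI", "CI")) {
    stop("unknown group name: ", group_name, call. = FALSE)
  }
  if (toi_mean < 0 || toi_mean > 100) stop("toi_mean must be in [0, 100]", call. = FALSE)
  if (moca_mean < 0 || moca_mean > 30) stop("moca_mean must be in [0, 30]", call. = FALSE)
  if (coupling_scale_vlf < 0 || coupling_scale_lf < 0) {
    stop("coupling scales must be >= 0", call. = FALSE)
  }
  structure(list(group_name = group_name,
                 coupling_scale_vlf = coupling_scale_vlf,
                 coupling_scale_lf = coupling_scale_lf,
                 toi_mean = toi_mean, toi_sd = toi_sd,
                 moca_mean = moca_mean, moca_sd = moca_sd),
            class = "group_profile")
}

#' Default group profiles
#'
#' MoCA distributions follow the reported cohort (NC 26.94 +/- 1.54,
#' MCI 20.60 +/- 3.42, CI 10.62 +/- 3.16 points). TOI means step down from
#' 65% (NC) through 62% (MCI) to 58% (CI) with a common 4% spread, and the
#' coupling scale rises from 1.0 through 1.5 to 2.0, encoding progressively
#' impaired autoregulation.
#'
#' @return Named list of [group_profile()] objects.
#' @export
default_group_profiles <- function() {
  list(
    NC = group_profile("NC", 1.0, 1.0, 65, 4, 26.94, 1.54),
    MCI = group_profile("MCI", 1.5, 1.5, 62, 4, 20.60, 3.42),
    CI = group_profile("CI", 2.0, 2.0, 58, 4, 10.62, 3.16)
  )
}

#' Measurement-artifact specification
#'
#' @param spike_rate Noise-spike events per minute (>= 0).
#' @param spike_amplitude_sd Spike amplitude SD in signal units.
#' @param motion_rate Motion-artifact events per minute (>= 0).
#' @param motion_step_sd Motion jump amplitude SD in signal units.
#' @param motion_tau Decay time constant of motion transients in seconds.
#' @return An `artifact_spec`.
#' @export
artifact_spec <- function(spike_rate = 2, spike_amplitude_sd = 5,
                          motion_rate = 0.3, motion_step_sd = 3,
                          motion_tau = 8) {
  vals <- c(spike_rate, spike_amplitude_sd, motion_rate, motion_step_sd)
  if (any(vals < 0)) stop("rates and amplitudes must be >= 0", call. = FALSE)
  structure(list(spike_rate = spike_rate,
                 spike_amplitude_sd = spike_amplitude_sd,
                 motion_rate = motion_rate, motion_step_sd = motion_step_sd,
                 motion_tau = motion_tau),
            class = "artifact_spec")
}

#' Simulate a pair of coupled stochastic phase oscillators
#'
#' Euler-Maruyama integration of
#' `dphi_m/dt = 2 * pi * w_m + q_m(phi_src, phi_dst) + noise`, with the
#' coupling acting on the target of `coupling$direction` only. Noise
#' increments are `N(0, D * step)` where `D` is the oscillator's phase noise
#' intensity. Returned phases are unwrapped. When no coupling term depends
#' on the driven oscillator's own phase the integration reduces to a
#' cumulative sum, which is used for speed; the general case is iterated.
#'
#' @param spec_a,spec_b [oscillator_spec()]s for oscillators `"a"` and `"b"`.
#' @param coupling A [coupling_spec()] whose `direction` references `"a"`
#'   and `"b"`, or `NULL` for uncoupled oscillators.
#' @param duration Record length in seconds (> 0).
#' @param step Integration step in seconds (> 0); `step * max frequency`
#'   must stay below 0.1 cycles and the record must contain at least 1000
#'   samples.
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with unwrapped `phi_a`, `phi_b`, `step`, and `fs`.
#' @export
simulate_phase_pair <- function(spec_a, spec_b, coupling = NULL,
                                duration, step, seed = 1) {
  stopifnot(inherits(spec_a, "oscillator_spec"),
            inherits(spec_b, "oscillator_spec"))
  if (duration <= 0 || step <= 0) {
    stop("duration and step must be positive", call. = FALSE)
  }
  fmax <- max(spec_a$natural_frequency, spec_b$natural_frequency)
  if (step * fmax >= 0.1) {
    stop("step too large: step * max frequency must be < 0.1 cycles",
         call. = FALSE)
  }
  n <- round(duration / step)
  if (n < 1000L) {
    stop("need at least 1000 samples (duration / step)", call. = FALSE)
  }
  if (!is.null(coupling)) {
    stopifnot(inherits(coupling, "coupling_spec"))
    if (!all(coupling$direction %in% c("a", "b"))) {
      stop("coupling references unknown oscillator: ",
           paste(coupling$direction, collapse = " -> "), call. = FALSE)
    }
  }
  set.seed(seed)
  noise_a <- stats::rnorm(n - 1, 0, sqrt(spec_a$phase_noise_intensity * step))
  noise_b <- stats::rnorm(n - 1, 0, sqrt(spec_b$phase_noise_intensity * step))
  wa <- 2 * pi * spec_a$natural_frequency
  wb <- 2 * pi * spec_b$natural_frequency
  src <- if (!is.null(coupling)) coupling$direction[1] else NA_character_
  dst <- if (!is.null(coupling)) coupling$direction[2] else NA_character_

  phi_a <- NULL; phi_b <- NULL
  if (is.null(coupling)) {
    phi_a <- c(0, cumsum(wa * step + noise_a))
    phi_b <- c(0, cumsum(wb * step + noise_b))
  } else {
    # integrate the free source first
    if (src == "a") {
      phi_a <- c(0, cumsum(wa * step + noise_a))
      phi_b <- integrate_driven(phi_a, wb, coupling, noise_b, step)
    } else {
      phi_b <- c(0, cumsum(wb * step + noise_b))
      phi_a <- integrate_driven(phi_b, wa, coupling, noise_a, step)
    }
  }
  list(phi_a = phi_a, phi_b = phi_b, step = step, fs = 1 / step)
}

# Euler-Maruyama for the driven oscillator given the source phase path.
integrate_driven <- function(phi_src, w_dst, coupling, noise, step) {
  cf <- coupling$coefficients
  n <- length(phi_src)
  if (all(cf$b == 0)) {
    # coupling independent of the driven phase: closed-form cumulative sum
    q <- eval_coupling(coupling, phi_src[-n], 0)
    return(c(0, cumsum((w_dst + q) * step + noise)))
  }
  phi <- numeric(n)
  for (i in seq_len(n - 1)) {
    q <- eval_coupling(coupling, phi_src[i], phi[i])
    phi[i + 1] <- phi[i] + (w_dst + q) * step + noise[i]
  }
  phi
}

#' Default oscillator specs for the study's three bands
#'
#' Centers of the canonical analysis bands: cardiac 1.1 Hz, VLF 0.04 Hz,
#' LF 0.1 Hz. Dynamical phase noise gives each oscillator a realistic slow
#' frequency wander.
#'
#' @param cardiac_noise,slow_noise Phase noise intensities (rad^2/s).
#' @return Named list of [oscillator_spec()]s: `cardiac`, `vlf`, `lf`.
#' @export
default_oscillators <- function(cardiac_noise = 0.01, slow_noise = 0.01) {
  list(
    cardiac = oscillator_spec(1.1, cardiac_noise, amplitude = 20),
    vlf = oscillator_spec(0.04, slow_noise, amplitude = 0.8),
    lf = oscillator_spec(0.1, slow_noise, amplitude = 0.5)
  )
}

#' Default base coupling: cardiac ABP phase driving a slow oscillation
#'
#' A single `sin(phi_ABP)` term of 0.25 rad/s, scaled per group and band by
#' the [group_profile()] coupling scales.
#'
#' @param value Coefficient of the `sin(phi_src)` term (rad/s).
#' @return A [coupling_spec()] from `"a"` (cardiac) to `"b"` (slow).
#' @export
default_base_coupling <- function(value = 0.25) {
  coupling_spec(c("a", "b"),
                data.frame(a = 1, b = 0, trig = "sin", value = value))
}

#' Render simulated phases into a measured recording
#'
#' Builds the measurement model: ABP at `fs_abp` is a baseline plus the
#' cardiac waveform `amplitude * cos(phi)` plus small leakage of the slow
#' components plus white measurement noise; each NIRS O2Hb channel at
#' `fs_nirs` is a baseline plus its VLF and LF waveforms plus noise plus
#' injected spikes and motion transients; HHb is constructed as
#' `o2hb_baseline * (100 - TOI) / TOI` plus small independent fluctuations,
#' where TOI is drawn from the group profile, so the clean baselines
#' reproduce the drawn TOI exactly.
#'
#' @param phases Named list with elements `cardiac`, `vlf_L`, `lf_L`,
#'   `vlf_R`, `lf_R`; each a list with `phase` (unwrapped, at `fs_nirs`) and
#'   `amplitude`.
#' @param group A [group_profile()].
#' @param artifacts An [artifact_spec()].
#' @param seed Integer seed.
#' @param fs_nirs,fs_abp Sampling rates (Hz).
#' @param abp_baseline,abp_noise_sd ABP baseline (mmHg) and noise SD.
#' @param abp_slow_amp Amplitude of slow-component leakage into ABP (mmHg).
#' @param o2hb_baseline,nirs_noise_sd O2Hb baseline (umol/L) and noise SD.
#' @param hhb_flux_sd SD of the independent HHb fluctuations.
#' @param subject_id Subject identifier.
#' @return A [recording()] with a `provenance` attribute recording the drawn
#'   TOI and injected artifact counts.
#' @export
synthesize_recording <- function(phases, group, artifacts = artifact_spec(),
                                 seed = 1, fs_nirs = 20, fs_abp = 1000,
                                 abp_baseline = 90, abp_noise_sd = 1,
                                 abp_slow_amp = 1, o2hb_baseline = 60,
                                 nirs_noise_sd = 0.1, hhb_flux_sd = 0.05,
                                 subject_id = "subject") {
  req <- c("cardiac", "vlf_L", "lf_L", "vlf_R", "lf_R")
  missing_c <- setdiff(req, names(phases))
  if (length(missing_c) > 0L) {
    stop("missing phase component(s): ", paste(missing_c, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  n_nirs <- length(phases$cardiac$phase)
  dur <- n_nirs / fs_nirs
  t_nirs <- (seq_len(n_nirs) - 1) / fs_nirs
  n_abp <- round(dur * fs_abp)
  t_abp <- (seq_len(n_abp) - 1) / fs_abp
  toi_draw <- min(max(stats::rnorm(1, group$toi_mean, group$toi_sd), 5), 95)

  # ABP: interpolate the unwrapped cardiac phase to the fast grid (the slow
  # components vary little within a NIRS sample, so their waveforms are
  # interpolated directly)
  interp <- function(v) stats::approx(t_nirs, v, xout = t_abp, rule = 2)$y
  abp <- abp_baseline +
    phases$cardiac$amplitude * cos(interp(phases$cardiac$phase)) +
    abp_slow_amp * interp(cos(phases$vlf_L$phase) +
                            cos(phases$lf_L$phase)) / 2 +
    (if (abp_noise_sd > 0) stats::rnorm(n_abp, 0, abp_noise_sd) else 0)

  hhb_baseline <- o2hb_baseline * (100 - toi_draw) / toi_draw
  counts <- list()
  mk_channel <- function(side) {
    vlf <- phases[[paste0("vlf_", side)]]
    lf <- phases[[paste0("lf_", side)]]
    o2 <- o2hb_baseline + vlf$amplitude * cos(vlf$phase) +
      lf$amplitude * cos(lf$phase) +
      (if (nirs_noise_sd > 0) stats::rnorm(n_nirs, 0, nirs_noise_sd) else 0)
    hb <- hhb_baseline - 0.3 * vlf$amplitude * cos(vlf$phase) +
      (if (hhb_flux_sd > 0) stats::rnorm(n_nirs, 0, hhb_flux_sd) else 0)
    # artifacts: spikes are single-sample outliers; motion transients are
    # abrupt jumps decaying exponentially, applied to both chromophores
    n_spike <- stats::rpois(1, artifacts$spike_rate * dur / 60)
    if (n_spike > 0) {
      at <- sample.int(n_nirs, n_spike, replace = TRUE)
      amp <- stats::rnorm(n_spike, 0, artifacts$spike_amplitude_sd)
      o2[at] <- o2[at] + amp
    }
    n_motion <- stats::rpois(1, artifacts$motion_rate * dur / 60)
    if (n_motion > 0) {
      at <- sort(sample.int(n_nirs, n_motion, replace = TRUE))
      amp <- stats::rnorm(n_motion, 0, artifacts$motion_step_sd)
      for (k in seq_len(n_motion)) {
        idx <- at[k]:n_nirs
        tr <- amp[k] * exp(-(t_nirs[idx] - t_nirs[at[k]]) / artifacts$motion_tau)
        o2[idx] <- o2[idx] + tr
        hb[idx] <- hb[idx] - 0.5 * tr
      }
    }
    counts[[side]] <<- list(spikes = n_spike, motion = n_motion)
    list(o2 = o2, hb = hb)
  }
  chL <- mk_channel("L")
  chR <- mk_channel("R")
  rec <- recording(list(
    O2Hb_L = time_series(chL$o2, fs_nirs, "O2Hb_L", "umol/L"),
    HHb_L = time_series(chL$hb, fs_nirs, "HHb_L", "umol/L"),
    O2Hb_R = time_series(chR$o2, fs_nirs, "O2Hb_R", "umol/L"),
    HHb_R = time_series(chR$hb, fs_nirs, "HHb_R", "umol/L"),
    ABP = time_series(abp, fs_abp, "ABP", "mmHg")
  ), subject_id = subject_id)
  attr(rec, "provenance") <- list(
    toi_draw = toi_draw, o2hb_baseline = o2hb_baseline,
    hhb_baseline = hhb_baseline, artifact_counts = counts, seed = seed
  )
  rec
}

#' Simulate one synthetic subject
#'
#' Simulates the cardiac ABP phase once, drives each of the four slow
#' oxyhemoglobin oscillators (VLF and LF, left and right channel) with the
#' base coupling scaled by the group's band-specific coupling scale, renders
#' the measured recording, and draws a MoCA score from the group profile
#' (clipped to [0, 30] and rounded). Ground-truth coupling parameters are
#' stored in the metadata for recovery tests.
#'
#' @param group A [group_profile()].
#' @param base_coupling A [coupling_spec()] (default
#'   [default_base_coupling()]).
#' @param seed Integer seed.
#' @param duration Record length in seconds (default 900).
#' @param step Phase integration step in seconds (default 0.05 = 20 Hz).
#' @param oscillators Output of [default_oscillators()] (or compatible).
#' @param artifacts An [artifact_spec()].
#' @param subject_id Subject identifier.
#' @param ... Passed to [synthesize_recording()].
#' @return List with `recording`, `metadata` (one-row data frame including
#'   `gt_` ground-truth columns), and the generative phases.
#' @export
simulate_subject <- function(group, base_coupling = default_base_coupling(),
                             seed = 1, duration = 900, step = 0.05,
                             oscillators = default_oscillators(),
                             artifacts = artifact_spec(),
                             subject_id = "subject", ...) {
  stopifnot(inherits(group, "group_profile"))
  if (!all(is.finite(c(group$coupling_scale_vlf, group$coupling_scale_lf)))) {
    stop("group coupling scales must be finite", call. = FALSE)
  }
  n <- round(duration / step)
  set.seed(seed)
  sub_seeds <- sample.int(2^31 - 2, 7)
  # cardiac phase (free oscillator)
  set.seed(sub_seeds[1])
  noise_c <- stats::rnorm(n - 1, 0,
                          sqrt(oscillators$cardiac$phase_noise_intensity * step))
  phi_card <- c(0, cumsum(2 * pi * oscillators$cardiac$natural_frequency * step +
                            noise_c))
  cpl <- list(
    vlf = scale_coupling(base_coupling, group$coupling_scale_vlf),
    lf = scale_coupling(base_coupling, group$coupling_scale_lf)
  )
  mk_slow <- function(band_name, seed_k) {
    spec <- oscillators[[band_name]]
    set.seed(seed_k)
    noise <- stats::rnorm(n - 1, 0, sqrt(spec$phase_noise_intensity * step))
    phi0 <- stats::runif(1, 0, 2 * pi)
    phi <- integrate_driven(phi_card, 2 * pi * spec$natural_frequency,
                            cpl[[band_name]], noise, step)
    list(phase = phi + phi0, amplitude = spec$amplitude)
  }
  phases <- list(
    cardiac = list(phase = phi_card, amplitude = oscillators$cardiac$amplitude),
    vlf_L = mk_slow("vlf", sub_seeds[2]),
    lf_L = mk_slow("lf", sub_seeds[3]),
    vlf_R = mk_slow("vlf", sub_seeds[4]),
    lf_R = mk_slow("lf", sub_seeds[5])
  )
  rec <- synthesize_recording(phases, group, artifacts, seed = sub_seeds[6],
                              subject_id = subject_id, fs_nirs = 1 / step, ...)
  set.seed(sub_seeds[7])
  moca <- round(min(max(stats::rnorm(1, group$moca_mean, group$moca_sd), 0), 30))
  assigned <- moca_group(moca)
  gt_vlf <- true_coupling_strength(cpl$vlf)
  gt_lf <- true_coupling_strength(cpl$lf)
  metadata <- data.frame(
    subject_id = subject_id, group = assigned,
    intended_group = group$group_name,
    band_crossed = assigned != group$group_name,
    moca = moca,
    gt_toi = attr(rec, "provenance")$toi_draw,
    gt_cs_vlf_L = gt_vlf, gt_cs_lf_L = gt_lf,
    gt_cs_vlf_R = gt_vlf, gt_cs_lf_R = gt_lf,
    stringsAsFactors = FALSE
  )
  list(recording = rec, metadata = metadata, phases = phases)
}

#' MoCA banding rule
#'
#' Scores of 26 or above are normal cognition (NC), 15-25 mild cognitive
#' impairment (MCI), 14 or less cognitive impairment (CI).
#'
#' @param score MoCA score(s), points.
#' @return Character vector of group labels.
#' @export
moca_group <- function(score) {
  ifelse(score >= 26, "NC", ifelse(score >= 15, "MCI", "CI"))
}

#' Simulate a synthetic cohort
#'
#' Generates `n_per_group` subjects per group with a counter-based seed
#' scheme (each subject's stream is a pure function of the cohort seed and
#' the subject index, independent of generation order). Group assignment in
#' the metadata follows the MoCA banding rule applied to the drawn scores,
#' with a flag when a drawn score crosses its profile's intended band.
#' Optionally writes the per-subject signal files and the metadata table.
#'
#' @param n_per_group Named vector/list of subject counts (names must be
#'   known group names present in `profiles`); all counts >= 1.
#' @param profiles Named list of [group_profile()]s
#'   (default [default_group_profiles()]).
#' @param seed Cohort seed.
#' @param write_dir If non-`NULL`, directory to write signal and metadata
#'   files into (see [write_recording()]).
#' @param ... Passed to [simulate_subject()].
#' @return List with `subjects` (list of [simulate_subject()] results) and
#'   `metadata` (data frame, one row per subject).
#' @export
simulate_cohort <- function(n_per_group, profiles = default_group_profiles(),
                            seed = 1, write_dir = NULL, ...) {
  n_per_group <- unlist(n_per_group)
  unknown <- setdiff(names(n_per_group), names(profiles))
  if (length(unknown) > 0L) {
    stop("unknown group name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(n_per_group < 1)) stop("counts must be >= 1", call. = FALSE)
  subjects <- list()
  meta <- list()
  idx <- 0L
  for (g in names(n_per_group)) {
    for (j in seq_len(n_per_group[[g]])) {
      idx <- idx + 1L
      sid <- sprintf("S%03d_%s", idx, g)
      sseed <- (seed + 131071 * idx) %% (2^31 - 1)
      subj <- simulate_subject(profiles[[g]], seed = sseed,
                               subject_id = sid, ...)
      subjects[[sid]] <- subj
      meta[[sid]] <- subj$metadata
    }
  }
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  if (!is.null(write_dir)) {
    dir.create(write_dir, recursive = TRUE, showWarnings = FALSE)
    for (sid in names(subjects)) {
      write_recording(subjects[[sid]]$recording, write_dir)
    }
    data.table::fwrite(metadata, file.path(write_dir, "metadata.csv"))
  }
  list(subjects = subjects, metadata = metadata)
}
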
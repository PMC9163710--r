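test_that("oscillator and coupling specs validate", {
  expect_error(oscillator_spec(0), "> 0")
  expect_error(oscillator_spec(1, -0.1), ">= 0")
  expect_error(coupling_spec(c("a", "b"),
                             data.frame(a = 0, b = 0, trig = "sin", value = 1)),
               "not a coupling term")
  expect_error(coupling_spec(c("a", "b"),
                             data.frame(a = 6, b = 0, trig = "sin", value = 1)),
               "k_max")
  cp <- default_base_coupling(0.25)
  expect_equal(true_coupling_strength(cp), 0.25)
  expect_equal(true_coupling_strength(scale_coupling(cp, 2)), 0.5)
})

test_that("phase pair simulation is deterministic and respects step limits", {
  a <- oscillator_spec(1.1, 0.01)
  b <- oscillator_spec(0.04, 0.01)
  s1 <- simulate_phase_pair(a, b, NULL, duration = 100, step = 0.05, seed = 5)
  s2 <- simulate_phase_pair(a, b, NULL, duration = 100, step = 0.05, seed = 5)
  expect_identical(s1, s2)
  s3 <- simulate_phase_pair(a, b, NULL, duration = 100, step = 0.05, seed = 6)
  expect_false(identical(s1$phi_a, s3$phi_a))
  expect_error(simulate_phase_pair(a, b, NULL, duration = 100, step = 0.2),
               "step too large")
  expect_error(simulate_phase_pair(b, b, NULL, duration = 10, step = 0.05),
               "1000 samples")
  expect_error(simulate_phase_pair(a, b,
                                   coupling_spec(c("a", "x"),
                                                 data.frame(a = 1, b = 0,
                                                            trig = "sin",
                                                            value = 0.1)),
                                   duration = 100, step = 0.05),
               "unknown oscillator")
})

test_that("zero coupling, zero noise gives exactly linear phases", {
  s <- simulate_phase_pair(oscillator_spec(1, 0), oscillator_spec(0.1, 0),
                           NULL, duration = 10, step = 0.01, seed = 1)
  t <- (0:999) * 0.01
  expect_equal(s$phi_a, 2 * pi * t, tolerance = 1e-9)
  expect_equal(s$phi_b, 2 * pi * 0.1 * t, tolerance = 1e-9)
})

test_that("strong sine coupling phase-locks detuned oscillators", {
  cp <- coupling_spec(c("a", "b"),
                      data.frame(a = 1, b = -1, trig = "sin", value = 2))
  s <- simulate_phase_pair(oscillator_spec(1.0, 0), oscillator_spec(0.95, 0),
                           cp, duration = 200, step = 0.01, seed = 1)
  d <- s$phi_a - s$phi_b
  tail_d <- d[15000:20000]
  expect_lt(max(tail_d) - min(tail_d), 1e-3)
  # locked difference satisfies the fixed-point condition sin(d) = 2 pi df / eps
  expect_equal(sin(mean(tail_d)), 2 * pi * 0.05 / 2, tolerance = 1e-3)
})

test_that("driven-phase regression recovers the injected coupling", {
  sim <- simulate_phase_pair(oscillator_spec(1.1, 0.01),
                             oscillator_spec(0.04, 0.01),
                             default_base_coupling(0.3),
                             duration = 900, step = 0.05, seed = 7)
  basis <- build_basis(2)
  cref <- ols_oracle(sim$phi_a, sim$phi_b, basis, sim$step)
  k_sin <- which(basis$terms$a == 1 & basis$terms$b == 0 &
                   basis$terms$trig == "sin")
  expect_equal(cref[k_sin], 0.3, tolerance = 0.05 / 0.3)
})

test_that("synthesize_recording builds consistent channels and provenance", {
  subj <- quick_subject(seed = 2, duration = 450)
  rec <- subj$recording
  expect_s3_class(rec, "nirs_recording")
  expect_equal(length(rec$channels$O2Hb_L), 9000L)
  expect_equal(length(rec$channels$ABP), 450000L)
  expect_equal(rec$channels$ABP$fs, 1000)
  prov <- attr(rec, "provenance")
  expect_true(prov$toi_draw >= 5 && prov$toi_draw <= 95)
  expect_named(prov$artifact_counts, c("L", "R"))
  # ABP stays in a physiological window around the 90 mmHg baseline
  expect_gt(min(rec$channels$ABP$values), 40)
  expect_lt(max(rec$channels$ABP$values), 140)
  # missing phase components are fatal
  expect_error(synthesize_recording(subj$phases[-2],
                                    default_group_profiles()$NC),
               "missing phase component")
})

test_that("subject simulation is deterministic with ground-truth metadata", {
  s1 <- quick_subject(seed = 10)
  s2 <- quick_subject(seed = 10)
  expect_identical(s1$recording$channels$O2Hb_L$values,
                   s2$recording$channels$O2Hb_L$values)
  expect_identical(s1$metadata, s2$metadata)
  md <- s1$metadata
  expect_equal(md$gt_cs_vlf_L, 0.25)  # NC scale 1.0 on the 0.25 rad/s base
  expect_true(md$moca >= 0 && md$moca <= 30)
  expect_equal(md$moca, round(md$moca))
  ci <- quick_subject(group = default_group_profiles()$CI, seed = 10)
  expect_equal(ci$metadata$gt_cs_vlf_L, 0.5)
  expect_false(identical(s1$recording$channels$O2Hb_L$values,
                         ci$recording$channels$O2Hb_L$values))
})

test_that("moca_group applies the banding rule at its edges", {
  expect_equal(moca_group(c(30, 26, 25, 15, 14, 0)),
               c("NC", "NC", "MCI", "MCI", "CI", "CI"))
})

test_that("cohort seeds are counter-based and order-independent", {
  co <- simulate_cohort(c(NC = 2, CI = 1), seed = 42, duration = 60,
                        artifacts = artifact_spec(spike_rate = 0,
                                                  motion_rate = 0))
  expect_equal(nrow(co$metadata), 3L)
  expect_equal(co$metadata$intended_group, c("NC", "NC", "CI"))
  # subject 3 must be a pure function of (seed, index): regenerate alone
  solo <- simulate_subject(default_group_profiles()$CI,
                           seed = (42 + 131071 * 3) %% (2^31 - 1),
                           subject_id = "S003_CI", duration = 60,
                           artifacts = artifact_spec(spike_rate = 0,
                                                     motion_rate = 0))
  expect_identical(co$subjects$S003_CI$recording$channels$O2Hb_L$values,
                   solo$recording$channels$O2Hb_L$values)
  expect_error(simulate_cohort(c(XX = 2)), "unknown group")
  expect_error(simulate_cohort(c(NC = 0)), ">= 1")
})

test_that("drawn MoCA scores follow the group profiles in the mean", {
  profiles <- default_group_profiles()
  co <- simulate_cohort(c(NC = 60, MCI = 60, CI = 60), seed = 9, duration = 60,
                        artifacts = artifact_spec(spike_rate = 0,
                                                  motion_rate = 0))
  md <- co$metadata
  for (g in names(profiles)) {
    m <- mean(md$moca[md$intended_group == g])
    expect_lt(abs(m - profiles[[g]]$moca_mean), 1.0)  # ~2 SE at n = 60
  }
  # band crossing is flagged where drawn scores leave the intended band
  expect_true(all(md$band_crossed ==
                    (md$group != md$intended_group)))
  # assigned groups follow the banding rule applied to the drawn score
  expect_equal(md$group, moca_group(md$moca))
})
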
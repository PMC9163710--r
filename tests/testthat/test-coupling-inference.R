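test_that("build_basis enumerates canonical terms", {
  b2 <- build_basis(2)
  expect_s3_class(b2, "coupling_basis")
  expect_equal(nrow(b2$terms), 25L)
  expect_equal(b2$terms$trig[1], "const")
  # canonical half-plane only: a > 0, or a = 0 with b > 0
  tm <- b2$terms[-1, ]
  expect_true(all(tm$a > 0 | (tm$a == 0 & tm$b > 0)))
  # every canonical pair appears exactly once with sin and once with cos
  key <- paste(tm$a, tm$b)
  expect_true(all(table(key) == 2))
  expect_equal(nrow(build_basis(3)$terms), 49L)
  expect_error(build_basis(0), "integer >= 1")
  expect_error(build_basis(2.5), "integer >= 1")
  # stable order: two calls agree exactly
  expect_identical(build_basis(2), build_basis(2))
})

test_that("inference recovers a known sine coupling against the OLS oracle", {
  sim <- simulate_phase_pair(oscillator_spec(1.1, 0.01),
                             oscillator_spec(0.04, 0.01),
                             default_base_coupling(0.3),
                             duration = 900, step = 0.05, seed = 7)
  basis <- build_basis(2)
  post <- infer_window(sim$phi_a, sim$phi_b, basis, step = sim$step)
  tm <- basis$terms
  k_sin <- which(tm$a == 1 & tm$b == 0 & tm$trig == "sin")
  expect_equal(post$c[k_sin, 2], 0.3, tolerance = 0.05 / 0.3)
  # OLS oracle agrees on the driven equation at moderate noise
  cref <- ols_oracle(sim$phi_a, sim$phi_b, basis, sim$step)
  expect_equal(post$c[, 2], unname(cref), tolerance = 0.02)
  # natural frequency lands in the constant term
  expect_equal(post$c[1, 2] / (2 * pi), 0.04, tolerance = 0.01)
  expect_equal(post$c[1, 1] / (2 * pi), 1.1, tolerance = 0.01)
  # coupling strengths: driven direction strong, reverse near noise floor
  cs_ao <- coupling_strength(post, "ao", basis)
  cs_oa <- coupling_strength(post, "oa", basis)
  expect_gt(cs_ao, 0.25)
  expect_lt(cs_oa, 0.1)
  expect_gt(directionality(cs_ao, cs_oa), 0.5)
})

test_that("zero-noise inference matches ordinary least squares", {
  # deterministic dynamics at a fine step: the posterior mean must collapse
  # onto the least-squares solution
  sim <- simulate_phase_pair(oscillator_spec(1.1, 0),
                             oscillator_spec(0.04, 0),
                             default_base_coupling(0.3),
                             duration = 60, step = 0.002, seed = 1)
  basis <- build_basis(2)
  post <- infer_window(sim$phi_a, sim$phi_b, basis, step = sim$step)
  cref <- ols_oracle(sim$phi_a, sim$phi_b, basis, sim$step)
  scale <- max(abs(cref))
  expect_lt(max(abs(post$c[, 2] - cref)) / scale, 1e-6)
})

test_that("inference is deterministic and 2*pi-shift invariant", {
  sim <- simulate_phase_pair(oscillator_spec(1.1, 0.01),
                             oscillator_spec(0.04, 0.01),
                             default_base_coupling(0.25),
                             duration = 400, step = 0.05, seed = 3)
  basis <- build_basis(2)
  p1 <- infer_window(sim$phi_a, sim$phi_b, basis, step = 0.05)
  p2 <- infer_window(sim$phi_a, sim$phi_b, basis, step = 0.05)
  expect_identical(p1$c, p2$c)
  p3 <- infer_window(sim$phi_a + 2 * pi, sim$phi_b - 4 * pi, basis, step = 0.05)
  expect_equal(p3$c, p1$c, tolerance = 1e-8)
})

test_that("posterior is calibrated under the uncoupled null", {
  basis <- build_basis(2)
  tm <- basis$terms
  cross_o <- which(tm$trig != "const" & tm$a != 0)  # cross terms, eq O
  L <- nrow(tm)
  fracs <- numeric(4)
  zmax <- numeric(4)
  for (k in 1:4) {
    sim <- simulate_phase_pair(oscillator_spec(1.1, 0.01),
                               oscillator_spec(0.04, 0.01), NULL,
                               duration = 400, step = 0.05, seed = 100 + k)
    post <- infer_window(sim$phi_a, sim$phi_b, basis, step = 0.05)
    sig <- sqrt(diag(solve(post$xi)))
    z <- post$c[cross_o, 2] / sig[L + cross_o]
    fracs[k] <- mean(abs(z) < 2)
    zmax[k] <- max(abs(z))
  }
  # roughly Gaussian calibration: most terms within 2 posterior SD, none wild
  expect_gte(mean(fracs), 0.85)
  expect_lt(max(zmax), 5)
})

test_that("sequential inference windows agree for stationary coupling", {
  sim <- simulate_phase_pair(oscillator_spec(1.1, 0.01),
                             oscillator_spec(0.04, 0.01),
                             default_base_coupling(0.3),
                             duration = 1200, step = 0.05, seed = 21)
  basis <- build_basis(2)
  posts <- infer_sequence(sim$phi_a, sim$phi_b, basis, window = 400,
                          step = 0.05)
  expect_length(posts, 3L)
  k_sin <- which(basis$terms$a == 1 & basis$terms$b == 0 &
                   basis$terms$trig == "sin")
  vals <- vapply(posts, function(p) p$c[k_sin, 2], numeric(1))
  sds <- vapply(posts, function(p) sqrt(solve(p$xi)[25 + k_sin, 25 + k_sin]),
                numeric(1))
  for (w in 2:3) {
    expect_lt(abs(vals[w] - vals[1]), 4 * sqrt(sds[w]^2 + sds[1]^2) + 0.02)
  }
  # with prop_const = 0 evidence accumulates: posterior variance shrinks
  posts0 <- infer_sequence(sim$phi_a, sim$phi_b, basis, window = 400,
                           prop_const = 0, step = 0.05)
  sds0 <- vapply(posts0, function(p) sqrt(solve(p$xi)[25 + k_sin, 25 + k_sin]),
                 numeric(1))
  expect_true(all(diff(sds0) < 0))
  # fallback: span shorter than the window gives one full-span window
  short <- infer_sequence(sim$phi_a[1:4000], sim$phi_b[1:4000], basis,
                          window = 400, step = 0.05)
  expect_length(short, 1L)
  expect_error(infer_sequence(sim$phi_a[1:4000], sim$phi_b[1:4000], basis,
                              window = 400, step = 0.05,
                              fallback_full_span = FALSE),
               "shorter than one window")
})

test_that("coupling_strength selects the right coefficients", {
  basis <- build_basis(2)
  tm <- basis$terms
  post <- list(c = matrix(0, nrow(tm), 2))
  k1 <- which(tm$a == 1 & tm$b == 0 & tm$trig == "sin")
  k2 <- which(tm$a == 2 & tm$b == -1 & tm$trig == "cos")
  k3 <- which(tm$a == 0 & tm$b == 1 & tm$trig == "sin")  # self term in eq O
  post$c[k1, 2] <- 0.3
  post$c[k2, 2] <- 0.4
  post$c[k3, 2] <- 9    # must be excluded from "ao"
  post$c[1, 2] <- 99    # constant always excluded
  expect_equal(coupling_strength(post, "ao", basis), 0.5)
  expect_equal(coupling_strength(post, "ao", basis, squared = TRUE), 0.25)
  # reverse direction reads b != 0 terms from equation A
  post2 <- list(c = matrix(0, nrow(tm), 2))
  post2$c[k2, 1] <- 0.12
  expect_equal(coupling_strength(post2, "oa", basis), 0.12)
})

test_that("directionality is the normalized asymmetry with guarded edges", {
  expect_equal(directionality(0.3, 0.1), 0.5)
  expect_equal(directionality(0.1, 0.3), -0.5)
  expect_equal(directionality(0.2, 0), 1)
  expect_error(directionality(0, 0), "undefined")
  expect_error(directionality(-0.1, 0.2), ">= 0")
})

test_that("coupling_surface reconstructs the fitted function", {
  basis <- build_basis(2)
  tm <- basis$terms
  post <- list(c = matrix(0, nrow(tm), 2))
  k1 <- which(tm$a == 1 & tm$b == 0 & tm$trig == "sin")
  post$c[k1, 2] <- 0.3
  surf <- coupling_surface(post, basis, resolution = 32)
  expect_equal(dim(surf$values), c(32L, 32L))
  expect_equal(surf$values, matrix(0.3 * sin(surf$grid), 32, 32),
               tolerance = 1e-12)
  expect_error(coupling_surface(post, basis, resolution = 8), ">= 16")
  m <- average_surface(list(surf, surf))
  expect_equal(m$values, surf$values)
})

test_that("subject_coupling summarizes windowed inference from phase series", {
  subj <- quick_subject(seed = 4, duration = 600)
  bands <- canonical_bands()
  abp20 <- downsample(subj$recording$channels$ABP, 20)
  phi_c <- extract_band_phase(abp20, bands$CARDIAC)
  phi_v <- extract_band_phase(subj$recording$channels$O2Hb_L, bands$VLF)
  basis <- build_basis(2)
  met <- subject_coupling(phi_c, phi_v, basis, window = 400)
  expect_true(all(c("cs_ao", "cs_oa", "cd", "n_windows") %in% names(met)))
  expect_gte(met$cs_ao, 0)
  expect_gte(met$cs_oa, 0)
  expect_true(met$cd >= -1 && met$cd <= 1)
})
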
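#' Fourier basis for a pair of coupled phase oscillators
#'
#' Enumerates the canonical Fourier terms used to expand the right-hand side
#' of each phase equation: a leading constant plus `sin` and `cos` of
#' `a * phi_A + b * phi_O` for every integer pair with `|a| <= K`,
#' `|b| <= K`, `(a, b) != (0, 0)`, restricted to canonical representatives
#' (`a > 0`, or `a = 0` and `b > 0`; the remaining half-plane is redundant up
#' to sign). For order `K` this yields `(2K + 1)^2` terms per equation
#' (25 at the default `K = 2`).
#'
#' @param K Basis order (>= 1).
#' @return A `coupling_basis`: list with `K` and a data frame `terms` with
#'   columns `a`, `b`, `trig` (`"const"`, `"sin"`, `"cos"`), in a stable
#'   canonical order.
#' @export
build_basis <- function(K) {
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K)) {
    stop("`K` must be an integer >= 1", call. = FALSE)
  }
  K <- as.integer(K)
  a_col <- 0L; b_col <- 0L; trig <- "const"
  for (a in 0:K) {
    for (b in -K:K) {
      if (a == 0L && b <= 0L) next
      a_col <- c(a_col, a, a)
      b_col <- c(b_col, b, b)
      trig <- c(trig, "sin", "cos")
    }
  }
  structure(
    list(K = K,
         terms = data.frame(a = a_col, b = b_col, trig = trig,
                            stringsAsFactors = FALSE)),
    class = "coupling_basis"
  )
}

# Evaluate the basis at phase samples: returns an L x N matrix.
eval_basis <- function(basis, phi_a, phi_o) {
  tm <- basis$terms
  L <- nrow(tm)
  out <- matrix(0, nrow = L, ncol = length(phi_a))
  out[1, ] <- 1
  for (k in 2:L) {
    arg <- tm$a[k] * phi_a + tm$b[k] * phi_o
    out[k, ] <- if (tm$trig[k] == "sin") sin(arg) else cos(arg)
  }
  out
}

# Derivative of each basis term with respect to one oscillator's phase.
eval_basis_deriv <- function(basis, phi_a, phi_o, wrt = c("a", "o")) {
  wrt <- match.arg(wrt)
  tm <- basis$terms
  L <- nrow(tm)
  out <- matrix(0, nrow = L, ncol = length(phi_a))
  mult <- if (wrt == "a") tm$a else tm$b
  for (k in 2:L) {
    if (mult[k] == 0) next
    arg <- tm$a[k] * phi_a + tm$b[k] * phi_o
    out[k, ] <- if (tm$trig[k] == "sin") mult[k] * cos(arg) else -mult[k] * sin(arg)
  }
  out
}

#' Dynamical Bayesian inference of the coupled phase model in one window
#'
#' Fits the two stochastic phase equations
#' `dphi_m/dt = sum_k c_k^(m) Phi_k(phi_A, phi_O) + noise` to a window of
#' unwrapped phase data by the stationary-point recursion for the Gaussian
#' posterior over the stacked coefficient vector: phase velocities are
#' forward differences over one sample, base functions are evaluated at
#' midpoint phases, and the recursion alternates (i) the 2 x 2 dynamical
#' noise matrix `E` from weighted residuals, (ii) the concentration
#' (inverse-covariance) update, (iii) the moment vector including the
#' midpoint drift correction `-(h/2) * sum dPhi/dphi_m`, and (iv) the
#' coefficient solve, until the coefficients change by less than `tol`
#' (relative) or `max_iter` sweeps. With no prior the recursion starts from
#' zero coefficients and a fully diffuse (zero) concentration.
#'
#' @param phi_a,phi_o Numeric vectors of unwrapped phases (cardiac ABP
#'   oscillation and slow oxyhemoglobin oscillation) on a common time grid,
#'   or `phase_series` objects (their common valid span is then used).
#' @param basis A [build_basis()] object.
#' @param prior Optional `coupling_posterior` from a previous window.
#' @param step Sample period in seconds.
#' @param tol Relative convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap (default 100).
#' @return A `coupling_posterior`: list with coefficient matrix `c`
#'   (L x 2, columns = equations for oscillators A and O), concentration
#'   `xi` (2L x 2L), noise matrix `E` (2 x 2), `iterations`, and the window
#'   sample count `n`.
#' @export
infer_window <- function(phi_a, phi_o, basis, prior = NULL, step,
                         tol = 1e-6, max_iter = 100) {
  if (inherits(phi_a, "phase_series") || inherits(phi_o, "phase_series")) {
    span <- common_valid_span(list(phi_a, phi_o))
    step <- 1 / phi_a$fs
    phi_a <- phase_in_span(phi_a, span)
    phi_o <- phase_in_span(phi_o, span)
  }
  stopifnot(is.numeric(phi_a), is.numeric(phi_o),
            length(phi_a) == length(phi_o), length(phi_a) >= 10L)
  stopifnot(inherits(basis, "coupling_basis"))
  h <- step
  n <- length(phi_a)
  # forward-difference velocities and midpoint phases
  pd <- rbind((phi_a[-1] - phi_a[-n]) / h,
              (phi_o[-1] - phi_o[-n]) / h)      # 2 x (n-1)
  ma <- (phi_a[-1] + phi_a[-n]) / 2
  mo <- (phi_o[-1] + phi_o[-n]) / 2
  Phi <- eval_basis(basis, ma, mo)              # L x (n-1)
  L <- nrow(Phi)
  N <- ncol(Phi)
  G <- Phi %*% t(Phi)                           # L x L
  s_mat <- Phi %*% t(pd)                        # L x 2 (sum Phi * phidot_m)
  v <- cbind(rowSums(eval_basis_deriv(basis, ma, mo, "a")),
             rowSums(eval_basis_deriv(basis, ma, mo, "o")))  # L x 2
  if (is.null(prior)) {
    c_prev <- matrix(0, L, 2)
    xi0 <- matrix(0, 2 * L, 2 * L)
    xc0 <- rep(0, 2 * L)
  } else {
    c_prev <- prior$c
    xi0 <- prior$xi
    xc0 <- as.numeric(xi0 %*% c(c_prev))
  }
  c_cur <- c_prev
  iter <- 0L
  repeat {
    iter <- iter + 1L
    res <- pd - t(c_cur) %*% Phi                # 2 x N residuals
    E <- (h / N) * (res %*% t(res))
    Einv <- tryCatch(solve(E), error = function(e) {
      stop("numerical conditioning: singular noise matrix; use a longer ",
           "window or smaller basis order K", call. = FALSE)
    })
    xi <- xi0 + h * kronecker(Einv, G)
    r <- xc0 +
      h * as.numeric(s_mat %*% Einv) -          # stacks (m = A, m = O)
      (h / 2) * as.numeric(v)
    c_new_vec <- tryCatch(solve(xi, r), error = function(e) {
      stop("numerical conditioning: singular concentration matrix; use a ",
           "longer window or smaller basis order K", call. = FALSE)
    })
    c_new <- matrix(c_new_vec, L, 2)
    delta <- sqrt(sum((c_new - c_cur)^2)) / max(sqrt(sum(c_new^2)), 1e-12)
    c_cur <- c_new
    if (delta < tol || iter >= max_iter) break
  }
  structure(
    list(c = c_cur, xi = xi, E = E, iterations = iter, n = n, step = h,
         basis_K = basis$K),
    class = "coupling_posterior"
  )
}

#' Sequential windowed inference with prior propagation
#'
#' Splits the common valid span into consecutive non-overlapping windows and
#' runs [infer_window()] on each, propagating each window's posterior as the
#' next window's prior with its covariance inflated by
#' `prop_const^2 * diag(c^2)` (information diffusion), so slow drift of the
#' coupling parameters can be tracked.
#'
#' @param phi_a,phi_o Unwrapped phase vectors on a common grid, or
#'   `phase_series` objects (restricted to their common valid span).
#' @param basis A [build_basis()] object.
#' @param window Window length in seconds.
#' @param prop_const Information-diffusion constant (default 0.2; 0 means
#'   evidence simply accumulates).
#' @param step Sample period in seconds (taken from the phase series when
#'   those are supplied).
#' @param fallback_full_span If `TRUE` (default), a span shorter than one
#'   window is analyzed as a single full-span window instead of erroring.
#' @param ... Passed to [infer_window()].
#' @return List of `coupling_posterior` objects, one per window.
#' @export
infer_sequence <- function(phi_a, phi_o, basis, window, prop_const = 0.2,
                           step = NULL, fallback_full_span = TRUE, ...) {
  if (inherits(phi_a, "phase_series") || inherits(phi_o, "phase_series")) {
    span <- common_valid_span(list(phi_a, phi_o))
    step <- 1 / phi_a$fs
    phi_a <- phase_in_span(phi_a, span)
    phi_o <- phase_in_span(phi_o, span)
  }
  if (is.null(step)) stop("`step` must be given for bare phase vectors",
                          call. = FALSE)
  n <- length(phi_a)
  wlen <- floor(window / step)
  n_win <- n %/% wlen
  if (n_win < 1L) {
    if (!fallback_full_span) {
      stop("span (", round(n * step, 1), " s) is shorter than one window (",
           window, " s)", call. = FALSE)
    }
    wlen <- n
    n_win <- 1L
  }
  posteriors <- vector("list", n_win)
  prior <- NULL
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * wlen + 1):(w * wlen)
    posteriors[[w]] <- infer_window(phi_a[idx], phi_o[idx], basis,
                                    prior = prior, step = step, ...)
    post <- posteriors[[w]]
    # diffuse the posterior into the next prior
    sigma <- tryCatch(solve(post$xi), error = function(e) NULL)
    if (!is.null(sigma)) {
      sigma <- sigma + diag(prop_const^2 * as.numeric(post$c)^2,
                            nrow = nrow(sigma))
      xi_next <- tryCatch(solve(sigma), error = function(e) post$xi)
      prior <- post
      prior$xi <- xi_next
    } else {
      prior <- post
    }
  }
  posteriors
}

#' Coupling strength from an inferred posterior
#'
#' Euclidean norm of the coefficients, in the target oscillator's equation,
#' of all base functions that depend on the source oscillator's phase
#' (`a != 0` for the ABP-to-oxyhemoglobin direction, `b != 0` for the
#' reverse); the constant and pure self terms are excluded. A `squared`
#' switch returns the plain sum of squares instead of its square root.
#'
#' @param posterior A `coupling_posterior`.
#' @param direction `"ao"` (cardiac ABP driving the slow oxyhemoglobin
#'   oscillation) or `"oa"`.
#' @param basis The [build_basis()] object used for inference.
#' @param squared Return the sum of squares instead of the norm.
#' @return Coupling strength in rad/s.
#' @export
coupling_strength <- function(posterior, direction = c("ao", "oa"), basis,
                              squared = FALSE) {
  direction <- match.arg(direction)
  tm <- basis$terms
  if (direction == "ao") {
    sel <- tm$trig != "const" & tm$a != 0
    coefs <- posterior$c[sel, 2]   # equation of oscillator O
  } else {
    sel <- tm$trig != "const" & tm$b != 0
    coefs <- posterior$c[sel, 1]   # equation of oscillator A
  }
  ss <- sum(coefs^2)
  if (squared) ss else sqrt(ss)
}

#' Coupling directionality index
#'
#' Normalized asymmetry `(cs_ao - cs_oa) / (cs_ao + cs_oa)`, in `[-1, 1]`;
#' positive when the ABP-to-oxyhemoglobin direction dominates.
#'
#' @param cs_ao,cs_oa Non-negative coupling strengths (rad/s).
#' @return Directionality index.
#' @export
directionality <- function(cs_ao, cs_oa) {
  if (cs_ao < 0 || cs_oa < 0) stop("coupling strengths must be >= 0",
                                   call. = FALSE)
  if (cs_ao + cs_oa == 0) {
    stop("undefined direction: both coupling strengths are zero",
         call. = FALSE)
  }
  (cs_ao - cs_oa) / (cs_ao + cs_oa)
}

#' Evaluate a coupling function on a phase grid
#'
#' Reconstructs `q_O(phi_ABP, phi_O2Hb) = sum_k c_k Phi_k` (constant term
#' excluded) on a uniform grid over `[0, 2*pi)^2`, for visualisation and
#' group averaging of coupling surfaces.
#'
#' @param posterior A `coupling_posterior`.
#' @param basis The matching [build_basis()] object.
#' @param resolution Grid points per axis (>= 16; default 48).
#' @param equation `"o"` (default) for the oxyhemoglobin equation, `"a"` for
#'   the ABP equation.
#' @return A `coupling_surface`: list with `grid` (phase vector) and
#'   `values` (resolution x resolution matrix; rows index `phi_ABP`, columns
#'   `phi_O2Hb`), in rad/s.
#' @export
coupling_surface <- function(posterior, basis, resolution = 48,
                             equation = c("o", "a")) {
  equation <- match.arg(equation)
  if (resolution < 16) stop("`resolution` must be >= 16", call. = FALSE)
  grid <- seq(0, 2 * pi, length.out = resolution + 1)[seq_len(resolution)]
  tm <- basis$terms
  cc <- posterior$c[, if (equation == "o") 2 else 1]
  values <- matrix(0, resolution, resolution)
  pa <- matrix(grid, resolution, resolution)        # rows: phi_ABP
  po <- matrix(grid, resolution, resolution, byrow = TRUE)
  for (k in 2:nrow(tm)) {
    if (cc[k] == 0) next
    arg <- tm$a[k] * pa + tm$b[k] * po
    values <- values + cc[k] * (if (tm$trig[k] == "sin") sin(arg) else cos(arg))
  }
  structure(list(grid = grid, values = values, equation = equation),
            class = "coupling_surface")
}

#' Pointwise mean of coupling surfaces
#'
#' @param surfaces List of `coupling_surface` objects on identical grids.
#' @return A `coupling_surface` holding the pointwise mean.
#' @export
average_surface <- function(surfaces) {
  stopifnot(length(surfaces) >= 1L)
  vals <- Reduce(`+`, lapply(surfaces, function(s) s$values)) / length(surfaces)
  out <- surfaces[[1]]
  out$values <- vals
  out
}

#' Per-subject coupling metrics for one phase pair
#'
#' Runs windowed inference over the common valid span of a cardiac and a
#' slow phase series and summarizes it into one row of metrics: the
#' per-subject coupling strength in each direction is the mean of the
#' windowed strengths, and the directionality index is computed from those
#' means.
#'
#' @param phi_a,phi_o `phase_series` (or bare phase vectors with `step`).
#' @param basis A [build_basis()] object.
#' @param window Window length in seconds.
#' @param prop_const Information-diffusion constant (default 0.2).
#' @param step Sample period (needed for bare vectors).
#' @param ... Passed to [infer_sequence()].
#' @return List with `cs_ao`, `cs_oa`, `cd`, `n_windows`, and the window
#'   posteriors.
#' @export
subject_coupling <- function(phi_a, phi_o, basis, window, prop_const = 0.2,
                             step = NULL, ...) {
  posts <- infer_sequence(phi_a, phi_o, basis, window, prop_const,
                          step = step, ...)
  cs_ao <- mean(vapply(posts, coupling_strength, numeric(1),
                       direction = "ao", basis = basis))
  cs_oa <- mean(vapply(posts, coupling_strength, numeric(1),
                       direction = "oa", basis = basis))
  list(cs_ao = cs_ao, cs_oa = cs_oa,
       cd = directionality(cs_ao, cs_oa),
       n_windows = length(posts), posteriors = posts)
}
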
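# Shared fixtures built in code.

tone <- function(f, duration = 900, fs = 20, phase0 = 0, amp = 1) {
  time_series(amp * cos(2 * pi * f * (0:(duration * fs - 1)) / fs + phase0), fs)
}

# Fitted slope of an unwrapped phase over its valid span (rad/s).
phase_slope <- function(ps) {
  v <- ps$valid_idx
  t <- (v - 1) / ps$fs
  unname(stats::coef(stats::lm(ps$phase[v] ~ t))[2])
}

# Independent OLS oracle: regress forward-difference phase velocities of the
# driven oscillator on the midpoint-evaluated Fourier basis.
ols_oracle <- function(phi_a, phi_o, basis, step) {
  n <- length(phi_a)
  pd <- (phi_o[-1] - phi_o[-n]) / step
  ma <- (phi_a[-1] + phi_a[-n]) / 2
  mo <- (phi_o[-1] + phi_o[-n]) / 2
  tm <- basis$terms
  X <- matrix(1, nrow = n - 1, ncol = nrow(tm))
  for (k in 2:nrow(tm)) {
    arg <- tm$a[k] * ma + tm$b[k] * mo
    X[, k] <- if (tm$trig[k] == "sin") sin(arg) else cos(arg)
  }
  qr.solve(X, pd)
}

# Brute-force ROC oracle: enumerate every distinct score as a cutoff
# (positive when score >= cutoff for direction "higher"), compute the ROC by
# counting, AUC by the trapezoid rule over the full curve, and pick the max-J
# cutoff breaking ties toward sensitivity.
roc_bruteforce <- function(scores, labels, direction = "higher") {
  s <- if (direction == "higher") scores else -scores
  labels <- as.logical(labels)
  cuts <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(cuts, function(th) sum(s[labels] >= th) / sum(labels), numeric(1))
  fpr <- vapply(cuts, function(th) sum(s[!labels] >= th) / sum(!labels), numeric(1))
  xs <- c(0, fpr, 1)
  ys <- c(0, tpr, 1)
  auc <- sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
  j <- tpr + (1 - fpr) - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(tpr[best])]
  list(auc = auc,
       threshold = if (direction == "higher") cuts[best] else -cuts[best],
       sensitivity = tpr[best], specificity = 1 - fpr[best], j = j[best])
}

# A small synthetic recording with controllable noise/artifacts.
quick_subject <- function(group = default_group_profiles()$NC, seed = 1,
                          duration = 450, ...) {
  simulate_subject(group, seed = seed, duration = duration, ...)
}

# Pipeline config scaled for short test recordings.
quick_config <- function(...) {
  pipeline_config(min_overlap = 300, n_boot = 200, ...)
}
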
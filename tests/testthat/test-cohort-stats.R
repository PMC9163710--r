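test_that("distribution checks behave on calibrated and violated inputs", {
  set.seed(1)
  x <- rnorm(60)
  g <- rep(c("NC", "MCI", "CI"), each = 20)
  chk <- distribution_checks(c(x[1:20], x[1:20], x[1:20]), g)
  expect_named(chk$ks, c("CI", "MCI", "NC"))
  # identical samples per group: zero between-group spread in variance
  expect_gt(chk$levene_p, 0.99)
  # a 5x variance inflation in one group is detected
  set.seed(2)
  v <- c(rnorm(40), rnorm(20, sd = 5))
  chk2 <- distribution_checks(v, g)
  expect_lt(chk2$levene_p, 0.01)
  expect_error(distribution_checks(rnorm(5), c("a", "a", "a", "b", "b")),
               "n >= 3")
  expect_error(distribution_checks(c(rep(1, 3), rnorm(3)),
                                   rep(c("a", "b"), each = 3)),
               "zero variance")
})

test_that("per-group KS against the fitted normal is calibrated", {
  g3 <- rep(c("NC", "MCI", "CI"), each = 100)
  # normal draws should rarely be rejected
  ps <- unlist(lapply(1:7, function(s) {
    set.seed(s)
    distribution_checks(rnorm(300), g3)$ks
  }))
  expect_gte(mean(ps > 0.05), 0.9)
  # a strongly bimodal group is rejected
  set.seed(3)
  bim <- c(rnorm(50, -3, 0.3), rnorm(50, 3, 0.3),  # first group bimodal
           rnorm(100), rnorm(100))
  expect_lt(distribution_checks(bim, g3)$ks[["NC"]], 1e-4)
})

test_that("anova_bonferroni orders groups clinically and flags pairs", {
  set.seed(4)
  g <- rep(c("NC", "MCI", "CI"), each = 20)
  v <- c(rnorm(20, 0, 0.1), rnorm(20, 0, 0.1), rnorm(20, 1, 0.1))
  res <- anova_bonferroni(v, g)
  expect_equal(res$corrected_alpha, 0.05 / 3)
  expect_equal(res$pairwise$comparison, c("NC-MCI", "NC-CI", "MCI-CI"))
  expect_equal(res$pairwise$significant, c(FALSE, TRUE, TRUE))
  expect_lt(res$anova_p, 1e-6)
  # pooled-variance Student's t by default: verify against t.test directly
  tt <- t.test(v[g == "NC"], v[g == "CI"], var.equal = TRUE)
  expect_equal(res$pairwise$p[2], tt$p.value)
  wt <- anova_bonferroni(v, g, welch = TRUE)
  expect_equal(wt$pairwise$p[2],
               t.test(v[g == "NC"], v[g == "CI"])$p.value)
  expect_error(anova_bonferroni(v[1:40], g[1:40]), "three groups")
})

test_that("pearson_cor matches cor.test and guards degenerate input", {
  set.seed(5)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30, 0, 0.5)
  pc <- pearson_cor(x, y)
  ct <- cor.test(x, y)
  expect_equal(pc$r, unname(ct$estimate))
  expect_equal(pc$p, ct$p.value)
  expect_error(pearson_cor(x, rep(1, 30)), "constant")
  expect_error(pearson_cor(x, y[1:10]), "equal-length")
})

test_that("roc_youden on a hand-checkable six-point dataset", {
  scores <- c(1, 2, 3, 4, 5, 6)
  labels <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  r <- roc_youden(scores, labels, "higher", n_boot = 50)
  # by enumeration: cutoff 5 gives sens 2/3, spec 1, J = 2/3 (the maximum
  # together with cutoff 3: sens 1, spec 2/3) -> tie broken toward sensitivity
  expect_equal(r$threshold, 3)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 2 / 3)
  expect_equal(r$j, 2 / 3)
  # AUC: pairs (pos > neg) = 8 of 9
  expect_equal(r$auc, 8 / 9)
})

test_that("roc_youden agrees with the brute-force oracle on random data", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(10:50, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- rnorm(n) + labels  # overlapping classes, ties unlikely
    if (s %% 3 == 0) scores <- round(scores)  # force ties regularly
    dir <- if (s %% 2 == 0) "higher" else "lower"
    r <- roc_youden(scores, labels, dir, n_boot = 10)
    bf <- roc_bruteforce(scores, labels, dir)
    expect_equal(r$auc, bf$auc, tolerance = 1e-12)
    expect_equal(r$threshold, bf$threshold)
    expect_equal(r$sensitivity, bf$sensitivity)
    expect_equal(r$specificity, bf$specificity)
  }
})

test_that("roc_youden AUC matches pROC and the CI behaves", {
  skip_if_not_installed("pROC")
  set.seed(6)
  labels <- rep(c(FALSE, TRUE), each = 40)
  scores <- rnorm(80) + labels * 1.5
  r <- roc_youden(scores, labels, "higher", n_boot = 500, seed = 2)
  pr <- pROC::roc(response = labels, predictor = scores,
                  direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
  expect_lt(r$ci[2] - r$ci[1], 0.35)
  # perfect separation
  rp <- roc_youden(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1), "higher",
                   n_boot = 20)
  expect_equal(rp$auc, 1)
  expect_equal(rp$sensitivity, 1)
  expect_equal(rp$specificity, 1)
  # null scores give AUC near 1/2
  set.seed(7)
  rn <- roc_youden(rnorm(200), rep(c(TRUE, FALSE), 100), "higher", n_boot = 20)
  expect_lt(abs(rn$auc - 0.5), 0.12)
  expect_error(roc_youden(1:5, rep(TRUE, 5), "higher"), "both classes")
})

test_that("roc direction = 'lower' reports thresholds on the original scale", {
  scores <- c(70, 68, 66, 60, 58, 56)        # TOI-like: low = impaired
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  r <- roc_youden(scores, labels, "lower", n_boot = 20)
  expect_equal(r$auc, 1)
  expect_true(r$threshold %in% scores)
  expect_gte(r$threshold, 56)
  expect_lte(r$threshold, 66)
})

test_that("group_report assembles the full statistical plan", {
  set.seed(8)
  n <- 15
  g <- rep(c("NC", "MCI", "CI"), each = n)
  mk <- function(means, sd) unlist(lapply(means, function(m) rnorm(n, m, sd)))
  metrics <- data.frame(
    group = g,
    moca = round(mk(c(27, 20.6, 10.6), 2)),
    ltoi = mk(c(65, 62, 58), 2), rtoi = mk(c(65, 62, 58), 2),
    mean_toi = mk(c(65, 62, 58), 2),
    cs_lpfc_vlf = mk(c(0.25, 0.37, 0.5), 0.04),
    cs_lpfc_lf = mk(c(0.25, 0.37, 0.5), 0.04),
    cs_rpfc_vlf = mk(c(0.25, 0.37, 0.5), 0.04),
    cs_rpfc_lf = mk(c(0.25, 0.37, 0.5), 0.04)
  )
  rep <- group_report(metrics, n_boot = 200, seed = 3)
  expect_s3_class(rep, "group_report")
  expect_named(rep$variables,
               c("ltoi", "rtoi", "mean_toi", "cs_lpfc_vlf", "cs_lpfc_lf",
                 "cs_rpfc_vlf", "cs_rpfc_lf"))
  av <- rep$variables$mean_toi$anova
  expect_lt(av$anova_p, 0.001)
  expect_true(av$pairwise$significant[av$pairwise$comparison == "NC-CI"])
  # TOI correlates positively, coupling negatively, with MoCA
  expect_gt(rep$correlations$mean_toi$r, 0.3)
  expect_lt(rep$correlations$cs_lpfc_vlf$r, -0.3)
  expect_lt(rep$correlations$cs_lpfc_vlf$p, 0.001)
  # ROC separates NC from MCI in the documented directions
  expect_gt(rep$roc$mean_toi$auc, 0.8)
  expect_gt(rep$roc$mean_cs$auc, 0.8)
  expect_output(print(rep), "pairwise")
  # determinism of the bootstrap
  rep2 <- group_report(metrics, n_boot = 200, seed = 3)
  expect_identical(rep$roc$mean_toi$ci, rep2$roc$mean_toi$ci)
})
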
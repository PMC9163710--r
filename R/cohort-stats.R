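#' Normality and homogeneity checks per group
#'
#' One-sample Kolmogorov-Smirnov test of each group against a normal
#' distribution with the group's own mean and SD, and a mean-centered Levene
#' test of variance homogeneity across groups.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`; each group needs at
#'   least 3 observations.
#' @return List with `ks` (named vector of per-group p-values) and
#'   `levene_p`.
#' @export
distribution_checks <- function(values, groups) {
  groups <- as.factor(groups)
  ns <- table(groups)
  if (any(ns < 3)) stop("each group needs n >= 3", call. = FALSE)
  ks <- vapply(levels(groups), function(g) {
    x <- values[groups == g]
    if (stats::sd(x) == 0) {
      stop("degenerate sample: zero variance in group ", g, call. = FALSE)
    }
    suppressWarnings(
      stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value
    )
  }, numeric(1))
  lev <- car::leveneTest(values ~ groups, center = mean)
  list(ks = ks, levene_p = lev[["Pr(>F)"]][1])
}

#' One-way ANOVA with Bonferroni-corrected pairwise t-tests
#'
#' Fixed-effects one-way ANOVA over three groups followed by the three
#' pairwise two-sample t-tests (NC-MCI, NC-CI, MCI-CI when those labels are
#' present; otherwise all pairs in level order). A comparison is flagged
#' significant when its raw p-value is below `family_alpha / 3` (0.0167 at
#' the default family alpha of 0.05). Pairwise tests use Student's t with
#' pooled variance by default; set `welch = TRUE` for the Welch variant.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (exactly 3 groups, each n >= 2).
#' @param family_alpha Family-wise alpha (default 0.05).
#' @param welch Use Welch's t instead of pooled-variance Student's t.
#' @return List with `anova_f`, `anova_p`, `corrected_alpha`, and a
#'   `pairwise` data frame (`comparison`, `p`, `significant`).
#' @export
anova_bonferroni <- function(values, groups, family_alpha = 0.05,
                             welch = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 3L) {
    stop("exactly three groups are required", call. = FALSE)
  }
  if (any(table(groups) < 2)) stop("each group needs n >= 2", call. = FALSE)
  pref <- c("NC", "MCI", "CI")
  lev <- if (all(levels(groups) %in% pref)) {
    pref[pref %in% levels(groups)]
  } else levels(groups)
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    g1 <- lev[pr[1]]; g2 <- lev[pr[2]]
    tt <- stats::t.test(values[groups == g1], values[groups == g2],
                        var.equal = !welch)
    data.frame(comparison = paste0(g1, "-", g2), p = tt$p.value,
               stringsAsFactors = FALSE)
  }))
  corrected <- family_alpha / 3
  pw$significant <- pw$p < corrected
  list(anova_f = tab[["F value"]][1], anova_p = tab[["Pr(>F)"]][1],
       corrected_alpha = corrected, pairwise = pw)
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @return List with `r` and `p`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length samples with n >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate sample: constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

# Empirical ROC over all distinct cutoffs for scores oriented so that
# higher values indicate the positive class. Cutoff rule: positive when
# score >= cutoff.
.roc_points <- function(scores, labels) {
  cuts <- sort(unique(scores))
  sens <- vapply(cuts, function(th) mean(scores[labels] >= th), numeric(1))
  spec <- vapply(cuts, function(th) mean(scores[!labels] < th), numeric(1))
  list(cuts = cuts, sens = sens, spec = spec)
}

# AUC as the Mann-Whitney statistic (ties counted 1/2); identical to the
# trapezoid rule over the empirical ROC.
.auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' ROC analysis with Youden's J optimal cutoff
#'
#' Empirical ROC over all distinct score cutoffs, AUC by the trapezoid rule,
#' the threshold maximizing Youden's J = sensitivity + specificity - 1 (ties
#' resolved in favor of sensitivity, the screening-friendly choice), and a
#' stratified-bootstrap percentile confidence interval for the AUC. The
#' `direction` argument states which tail indicates the positive (impaired)
#' class: TOI below threshold and coupling strength above threshold flag
#' impairment.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) vector; `TRUE` = positive class. Both
#'   classes must be present.
#' @param direction `"higher"` if larger scores indicate the positive class,
#'   `"lower"` otherwise.
#' @param n_boot Bootstrap resamples for the CI (default 2000).
#' @param conf Confidence level (default 0.95).
#' @param seed Seed for the bootstrap.
#' @return List with `auc`, `ci`, `threshold` (on the original score scale),
#'   `sensitivity`, `specificity`, and `j`.
#' @export
roc_youden <- function(scores, labels, direction = c("higher", "lower"),
                       n_boot = 2000, conf = 0.95, seed = 1) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  s <- if (direction == "higher") scores else -scores
  pts <- .roc_points(s, labels)
  j <- pts$sens + pts$spec - 1
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[which.max(pts$sens[best])]
  auc <- .auc(s, labels)
  set.seed(seed)
  ipos <- which(labels); ineg <- which(!labels)
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(ipos, replace = TRUE), sample(ineg, replace = TRUE))
    .auc(s[idx], labels[idx])
  }, numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
  thr <- pts$cuts[best]
  list(auc = auc, ci = ci,
       threshold = if (direction == "higher") thr else -thr,
       sensitivity = pts$sens[best], specificity = pts$spec[best],
       j = j[best])
}

# Render a p-value for human-readable summaries.
format_p <- function(p) {
  if (p < 1e-4) "<0.001" else sprintf("%.4f", p)
}

#' Cohort-level group report
#'
#' Runs the full statistical plan over a subject-metrics table: per-variable
#' distribution checks, one-way ANOVA with Bonferroni pairwise tests,
#' Pearson correlations of each variable with the MoCA score, and ROC/Youden
#' analysis separating the MCI from the NC group using mean TOI (lower =
#' impaired) and the bilateral mean coupling strength (higher = impaired).
#'
#' @param metrics Data frame with columns `group`, `moca`, `ltoi`, `rtoi`,
#'   `mean_toi`, and the `cs_*` coupling-strength columns.
#' @param family_alpha Family-wise alpha for the pairwise tests.
#' @param n_boot Bootstrap resamples for ROC CIs.
#' @param seed Seed for the bootstrap.
#' @param variables Variables to analyze (default: all TOI and CS columns
#'   present).
#' @return A `group_report` list with `variables` (per-variable stats),
#'   `correlations`, and `roc`.
#' @export
group_report <- function(metrics, family_alpha = 0.05, n_boot = 2000,
                         seed = 1,
                         variables = intersect(
                           c("ltoi", "rtoi", "mean_toi",
                             "cs_lpfc_vlf", "cs_lpfc_lf",
                             "cs_rpfc_vlf", "cs_rpfc_lf"),
                           names(metrics))) {
  stopifnot(all(c("group", "moca") %in% names(metrics)))
  per_var <- lapply(variables, function(v) {
    x <- metrics[[v]]
    res <- list(variable = v)
    res$checks <- tryCatch(distribution_checks(x, metrics$group),
                           error = function(e) conditionMessage(e))
    res$anova <- tryCatch(anova_bonferroni(x, metrics$group, family_alpha),
                          error = function(e) conditionMessage(e))
    res
  })
  names(per_var) <- variables
  correlations <- lapply(variables, function(v) {
    tryCatch(pearson_cor(metrics$moca, metrics[[v]]),
             error = function(e) conditionMessage(e))
  })
  names(correlations) <- variables
  roc <- list()
  sub <- metrics[metrics$group %in% c("NC", "MCI"), , drop = FALSE]
  if (nrow(sub) > 0 && length(unique(sub$group)) == 2L) {
    lab <- sub$group == "MCI"
    if ("mean_toi" %in% names(sub)) {
      roc$mean_toi <- roc_youden(sub$mean_toi, lab, direction = "lower",
                                 n_boot = n_boot, seed = seed)
    }
    cs_cols <- intersect(c("cs_lpfc_vlf", "cs_lpfc_lf",
                           "cs_rpfc_vlf", "cs_rpfc_lf"), names(sub))
    if (length(cs_cols) > 0) {
      cs_mean <- rowMeans(sub[, cs_cols, drop = FALSE])
      roc$mean_cs <- roc_youden(cs_mean, lab, direction = "higher",
                                n_boot = n_boot, seed = seed)
    }
  }
  structure(list(variables = per_var, correlations = correlations, roc = roc,
                 family_alpha = family_alpha),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat("Cohort group report (corrected pairwise alpha = ",
      sprintf("%.4f", x$family_alpha / 3), ")\n\n", sep = "")
  for (v in names(x$variables)) {
    a <- x$variables[[v]]$anova
    if (is.character(a)) {
      cat(sprintf("%-12s %s\n", v, a)); next
    }
    cat(sprintf("%-12s F = %6.2f, p = %s; pairwise: %s\n", v,
                a$anova_f, format_p(a$anova_p),
                paste(sprintf("%s %s%s", a$pairwise$comparison,
                              vapply(a$pairwise$p, format_p, character(1)),
                              ifelse(a$pairwise$significant, "*", "")),
                      collapse = ", ")))
  }
  cat("\nCorrelations with MoCA:\n")
  for (v in names(x$correlations)) {
    ct <- x$correlations[[v]]
    if (is.character(ct)) next
    cat(sprintf("  %-12s r = %6.3f, p = %s\n", v, ct$r, format_p(ct$p)))
  }
  if (length(x$roc) > 0) {
    cat("\nROC (NC vs MCI):\n")
    for (v in names(x$roc)) {
      r <- x$roc[[v]]
      cat(sprintf("  %-10s AUC = %.2f (%.2f, %.2f), threshold = %.3g, sens = %.1f%%, spec = %.1f%%\n",
                  v, r$auc, r$ci[1], r$ci[2], r$threshold,
                  100 * r$sensitivity, 100 * r$specificity))
    }
  }
  invisible(x)
}
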
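#' ROC curve
#'
#' Computes the ROC curve of a score against binary labels over all
#' realized thresholds. Classification at a threshold `t` predicts
#' admission when `score >= t`; tied scores are grouped at a single
#' threshold. The curve starts at (0, 0) (threshold `Inf`) and ends at
#' (1, 1) (the minimum score); TPR and FPR are non-decreasing as the
#' threshold decreases.
#'
#' @param scores Numeric score vector (higher = more likely admitted).
#' @param labels Binary vector with both classes present.
#' @return A `roc_curve`: data frame of `threshold, tpr, fpr` (thresholds
#'   descending, `Inf` first) with attributes `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  if (anyNA(scores)) stop("scores contain missing values")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("degenerate input: both classes must be present")
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  # group ties: cumulative counts at the last element of each tie block
  last_of_block <- c(s[-length(s)] != s[-1L], TRUE)
  tp <- cumsum(y)[last_of_block]
  fp <- cumsum(1L - y)[last_of_block]
  curve <- data.frame(threshold = c(Inf, s[last_of_block]),
                      tpr = c(0, tp / n_pos),
                      fpr = c(0, fp / n_neg))
  structure(curve, class = c("roc_curve", "data.frame"),
            n_pos = n_pos, n_neg = n_neg)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, %d positives / %d negatives, AUC %.4f\n",
              nrow(x) - 1L, attr(x, "n_pos"), attr(x, "n_neg"), auc(x)))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under a [roc_curve()], equal to the tie-corrected
#' pair-counting statistic `(concordant + ties/2) / (n_pos * n_neg)`.
#'
#' @param roc A `roc_curve`.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  sum(diff(roc$fpr) * (roc$tpr[-1L] + roc$tpr[-nrow(roc)]) / 2)
}

.midranks <- function(x) rank(x, ties.method = "average")

#' AUC with a 95% confidence interval
#'
#' The point estimate is the tie-corrected Mann-Whitney statistic: the
#' probability that a random admitted patient scores above a random
#' discharged one, counting ties as one half. The default interval is the
#' DeLong asymptotic-covariance construction (structural components per
#' observation, Wald interval clamped to `[0, 1]`); a stratified bootstrap
#' is available as an alternative.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels, both classes present.
#' @param conf_level Confidence level (default 0.95).
#' @param method `"delong"` (default) or `"bootstrap"`.
#' @param boot_reps,boot_seed Bootstrap replicates and seed (bootstrap
#'   method only).
#' @return An `auc_result`: list with `auc`, `ci_low`, `ci_high`,
#'   `method`, `n_pos`, `n_neg`.
#' @export
auc_with_ci <- function(scores, labels, conf_level = 0.95,
                        method = c("delong", "bootstrap"),
                        boot_reps = 2000L, boot_seed = 1L) {
  method <- match.arg(method)
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L) {
    stop("degenerate input: both classes must be present")
  }
  r_all <- .midranks(c(pos, neg))
  theta <- (sum(r_all[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
  z <- qnorm(1 - (1 - conf_level) / 2)
  if (method == "delong") {
    v10 <- (r_all[seq_len(m)] - .midranks(pos)) / n
    v01 <- 1 - (r_all[m + seq_len(n)] - .midranks(neg)) / m
    s10 <- if (m > 1L) stats::var(v10) else 0
    s01 <- if (n > 1L) stats::var(v01) else 0
    se <- sqrt(s10 / m + s01 / n)
    lo <- max(0, theta - z * se)
    hi <- min(1, theta + z * se)
  } else {
    old <- .save_rng_state(); on.exit(.restore_rng_state(old), add = TRUE)
    set.seed(as.integer(boot_seed))
    reps <- vapply(seq_len(boot_reps), function(i) {
      p <- sample(pos, m, replace = TRUE)
      q <- sample(neg, n, replace = TRUE)
      r <- .midranks(c(p, q))
      (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
    }, numeric(1))
    qs <- stats::quantile(reps, c((1 - conf_level) / 2,
                                  1 - (1 - conf_level) / 2), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  structure(list(auc = theta, ci_low = lo, ci_high = hi,
                 conf_level = conf_level, method = method,
                 n_pos = m, n_neg = n),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC %.4f (%.0f%% CI %.4f-%.4f, %s; %d pos / %d neg)\n",
              x$auc, 100 * x$conf_level, x$ci_low, x$ci_high, x$method,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the realized
#' thresholds of the ROC curve. Ties in J are broken toward higher
#' sensitivity (triage prefers catching admissions), then toward the
#' lowest threshold, making the choice deterministic.
#'
#' @param roc A [roc_curve()].
#' @return List with `cutoff` (a realized threshold; predict admission
#'   when `score >= cutoff`) and `J`.
#' @export
youden_optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$tpr - roc$fpr
  # J values are ratios of small integer counts; differences below 1e-9
  # can only be rounding noise of mathematically tied values
  best <- which(j >= max(j) - 1e-9)
  best <- best[roc$tpr[best] == max(roc$tpr[best])]
  best <- best[which.min(roc$threshold[best])]
  cutoff <- roc$threshold[best]
  if (!is.finite(cutoff)) cutoff <- max(roc$threshold[is.finite(roc$threshold)])
  list(cutoff = cutoff, J = max(j))
}

#' Wilson score interval for a proportion
#'
#' @param x Successes.
#' @param n Trials.
#' @param conf_level Confidence level (default 0.95).
#' @return Numeric `c(low, high)`; `c(NA, NA)` when `n == 0`.
#' @export
wilson_ci <- function(x, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

#' Confusion metrics at a cutoff
#'
#' Classifies `score >= cutoff` as predicted admission and reports
#' sensitivity, specificity, PPV and NPV, each with a Wilson 95%
#' interval, plus the confusion counts. A cutoff that leaves the
#' predicted-positive (or predicted-negative) set empty makes PPV (NPV)
#' undefined; the metric is returned as `NA` with an `undefined` flag
#' rather than fabricated.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels, both classes present.
#' @param cutoff Classification threshold.
#' @param conf_level Confidence level for the Wilson intervals.
#' @return A `cutoff_metrics` list: `cutoff`, confusion counts, and for
#'   each metric a list `estimate, ci_low, ci_high, undefined`.
#' @export
confusion_metrics_at_cutoff <- function(scores, labels, cutoff,
                                        conf_level = 0.95) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L) {
    stop("degenerate input: both classes must be present")
  }
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  tn <- sum(!pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  metric <- function(x, n) {
    if (n == 0) {
      list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           undefined = TRUE)
    } else {
      ci <- wilson_ci(x, n, conf_level)
      list(estimate = x / n, ci_low = ci[1], ci_high = ci[2],
           undefined = FALSE)
    }
  }
  structure(list(cutoff = cutoff,
                 counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 sensitivity = metric(tp, tp + fn),
                 specificity = metric(tn, tn + fp),
                 ppv = metric(tp, tp + fp),
                 npv = metric(tn, tn + fn),
                 conf_level = conf_level),
            class = "cutoff_metrics")
}

#' @export
print.cutoff_metrics <- function(x, ...) {
  cat(sprintf("Operating point at cutoff %.4f\n", x$cutoff))
  cat(sprintf("  counts: TP %d, FP %d, TN %d, FN %d\n",
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"]))
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    mm <- x[[m]]
    if (mm$undefined) {
      cat(sprintf("  %-12s undefined (empty denominator)\n", m))
    } else {
      cat(sprintf("  %-12s %.4f (%.0f%% CI %.4f-%.4f)\n", m, mm$estimate,
                  100 * x$conf_level, mm$ci_low, mm$ci_high))
    }
  }
  invisible(x)
}

#' Full validation evaluation
#'
#' Convenience wrapper producing the complete results surface for one
#' model on one validation set: ROC curve, AUC with CI, the Youden
#' operating point and its confusion metrics.
#'
#' @param scores Predicted admission probabilities.
#' @param labels Binary admission labels.
#' @return An `evaluation_report` list: `roc`, `auc`, `cutoff`, `J`,
#'   `metrics`, `n`.
#' @export
evaluate_predictions <- function(scores, labels) {
  roc <- roc_curve(scores, labels)
  au <- auc_with_ci(scores, labels)
  yj <- youden_optimal_cutoff(roc)
  structure(list(roc = roc, auc = au, cutoff = yj$cutoff, J = yj$J,
                 metrics = confusion_metrics_at_cutoff(scores, labels,
                                                       yj$cutoff),
                 n = length(labels)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Validation evaluation (n =", x$n, ")\n")
  print(x$auc)
  cat(sprintf("Youden cutoff %.4f (J = %.4f)\n", x$cutoff, x$J))
  print(x$metrics)
  invisible(x)
}

#' Evaluate the model per chief-complaint category
#'
#' Applies the single all-patient model (no refitting) to each
#' chief-complaint category of the validation set separately and reports
#' per-category ROC and AUC with CI. Categories with fewer than two
#' records of either class are flagged degenerate and carry no AUC
#' (small subgroups, such as environmental emergencies, stay in the
#' report rather than erroring).
#'
#' @param model A trained `admission_model`.
#' @param validation Nonempty post-filter validation visits.
#' @param table The `cc_risk_table` fitted on the training set.
#' @return A `subgroup_report`: named list over `all` plus the four
#'   categories, each with `n`, `n_pos`, `degenerate`, and (when not
#'   degenerate) `auc` and `roc`.
#' @export
evaluate_subgroups <- function(model, validation, table) {
  stopifnot(inherits(model, "admission_model"), is.data.frame(validation))
  if (nrow(validation) == 0L) stop("validation set is empty")
  x <- encode_features(validation, table, model$feature_subset)
  scores <- predict_admission_probability(model, x)
  labels <- admission_labels(validation)
  one <- function(idx) {
    s <- scores[idx]; y <- labels[idx]
    n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
    if (n_pos < 2L || n_neg < 2L) {
      list(n = length(idx), n_pos = n_pos, n_neg = n_neg,
           degenerate = TRUE, auc = NULL, roc = NULL)
    } else {
      list(n = length(idx), n_pos = n_pos, n_neg = n_neg,
           degenerate = FALSE, auc = auc_with_ci(s, y),
           roc = roc_curve(s, y))
    }
  }
  groups <- c(list(all = seq_len(nrow(validation))),
              lapply(setNames(nm = cc_categories()),
                     function(g) which(validation$cc_category == g)))
  structure(lapply(groups, one), class = "subgroup_report")
}

#' @export
print.subgroup_report <- function(x, ...) {
  cat("Subgroup evaluation:\n")
  for (nm in names(x)) {
    g <- x[[nm]]
    if (g$degenerate) {
      cat(sprintf("  %-20s n=%d (degenerate: %d admitted / %d discharged)\n",
                  nm, g$n, g$n_pos, g$n_neg))
    } else {
      cat(sprintf("  %-20s n=%d AUC %.4f (95%% CI %.4f-%.4f)\n",
                  nm, g$n, g$auc$auc, g$auc$ci_low, g$auc$ci_high))
    }
  }
  invisible(x)
}

#' Write ROC curves as CSV
#'
#' @param report A `subgroup_report` or single `roc_curve`.
#' @param path Output CSV (columns `group, threshold, fpr, tpr`).
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(report, path) {
  rows <- if (inherits(report, "roc_curve")) {
    cbind(group = "all", as.data.frame(report))
  } else {
    do.call(rbind, lapply(names(report), function(nm) {
      if (is.null(report[[nm]]$roc)) return(NULL)
      cbind(group = nm, as.data.frame(report[[nm]]$roc))
    }))
  }
  write.csv(rows[c("group", "threshold", "fpr", "tpr")], path,
            row.names = FALSE)
  invisible(path)
}

#' Plot the ROC panels
#'
#' One panel per group of a [evaluate_subgroups()] report (all patients
#' plus the four chief-complaint categories); degenerate groups are
#' omitted.
#'
#' @param report A `subgroup_report`.
#' @param path Optional file to save to (via [ggplot2::ggsave()]).
#' @return The ggplot object, invisibly.
#' @export
plot_roc_panels <- function(report, path = NULL) {
  stopifnot(inherits(report, "subgroup_report"))
  rows <- do.call(rbind, lapply(names(report), function(nm) {
    g <- report[[nm]]
    if (g$degenerate) return(NULL)
    data.frame(group = sprintf("%s (AUC %.3f)", nm, g$auc$auc),
               fpr = g$roc$fpr, tpr = g$roc$tpr)
  }))
  p <- ggplot2::ggplot(rows, ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_bw()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 8, height = 6)
  invisible(p)
}
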
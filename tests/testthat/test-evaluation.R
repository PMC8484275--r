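# O(n^2) pair-counting oracle: P(score_pos > score_neg) + 0.5 P(tie)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(pos) * length(neg))
}

# exhaustive Youden scan over every distinct score as a threshold
youden_bruteforce <- function(scores, labels) {
  best_j <- -Inf; best_cut <- NA; best_sens <- -1
  for (t in sort(unique(scores), decreasing = TRUE)) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    if (j > best_j + 1e-9 ||
        (abs(j - best_j) <= 1e-9 &&
         (sens > best_sens ||
          (sens == best_sens && t < best_cut)))) {
      best_j <- j; best_cut <- t; best_sens <- sens
    }
  }
  list(cutoff = best_cut, J = best_j)
}

test_that("ROC curve handles separable, tied and worked cases", {
  r1 <- roc_curve(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_true(any(r1$fpr == 0 & r1$tpr == 1))
  expect_equal(auc(r1), 1)

  r2 <- roc_curve(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(auc(r2), 0.5)
  expect_equal(nrow(r2), 2L)  # one tie-grouped threshold plus the origin

  r3 <- roc_curve(c(0.9, 0.4, 0.6, 0.2), c(1, 0, 1, 0))
  expect_equal(auc(r3), 1)
  expect_equal(auc(r3), auc_bruteforce(c(0.9, 0.4, 0.6, 0.2), c(1, 0, 1, 0)))

  # endpoints and monotonicity
  expect_equal(r3$tpr[1], 0); expect_equal(r3$fpr[1], 0)
  expect_equal(r3$tpr[nrow(r3)], 1); expect_equal(r3$fpr[nrow(r3)], 1)
  expect_true(all(diff(r3$tpr) >= 0) && all(diff(r3$fpr) >= 0))

  expect_error(roc_curve(1:4, rep(1, 4)), "both classes")
})

test_that("AUC equals O(n^2) pair counting on 500 random small instances", {
  set.seed(601)
  for (i in 1:500) {
    n <- sample(4:40, 1)
    scores <- if (i %% 3 == 0) sample(1:5, n, replace = TRUE) / 5 else runif(n)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(auc_with_ci(scores, labels)$auc,
                 auc_bruteforce(scores, labels))
    expect_equal(auc(roc_curve(scores, labels)),
                 auc_bruteforce(scores, labels))
  }
})

test_that("Youden cutoff equals the exhaustive scan on 500 random instances", {
  set.seed(602)
  for (i in 1:500) {
    n <- sample(6:40, 1)
    scores <- if (i %% 4 == 0) sample(1:6, n, replace = TRUE) / 6 else
      round(runif(n), 2)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    got <- youden_optimal_cutoff(roc_curve(scores, labels))
    want <- youden_bruteforce(scores, labels)
    expect_equal(got$J, want$J, tolerance = 1e-12)
    expect_equal(got$cutoff, want$cutoff)
  }
})

test_that("Youden worked fixture and degenerate cases", {
  scores <- c(0.9, 0.8, 0.7, 0.4, 0.3, 0.1)
  labels <- c(1, 1, 0, 1, 0, 0)
  got <- youden_optimal_cutoff(roc_curve(scores, labels))
  want <- youden_bruteforce(scores, labels)
  expect_equal(got$cutoff, want$cutoff)
  expect_equal(got$J, want$J)

  sep <- youden_optimal_cutoff(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)))
  expect_equal(sep$J, 1)
  expect_true(sep$cutoff > 0.2 && sep$cutoff <= 0.8)

  tie <- youden_optimal_cutoff(roc_curve(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)))
  expect_equal(tie$J, 0)
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(603)
  for (i in 1:20) {
    scores <- runif(60)
    labels <- rbinom(60, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    a0 <- auc_with_ci(scores, labels)$auc
    expect_equal(auc_with_ci(exp(scores), labels)$auc, a0)
    expect_equal(auc_with_ci(rank(scores), labels)$auc, a0)
    # reversal identity for tie-free scores
    expect_equal(auc_with_ci(-scores, labels)$auc, 1 - a0)
  }
})

test_that("DeLong interval matches the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(604)
  for (i in 1:10) {
    n <- 300
    labels <- rbinom(n, 1, 0.3)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- rnorm(n, mean = labels)
    got <- auc_with_ci(scores, labels)
    ref <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE),
                        method = "delong")
    expect_equal(got$auc, as.numeric(ref[2]), tolerance = 1e-10)
    expect_equal(got$ci_low, as.numeric(ref[1]), tolerance = 1e-8)
    expect_equal(got$ci_high, as.numeric(ref[3]), tolerance = 1e-8)
  }
})

test_that("null-score AUC interval covers 0.5 in most seeded replicates", {
  set.seed(605)
  cover <- vapply(1:100, function(i) {
    scores <- runif(200)
    labels <- rbinom(200, 1, 0.3)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    ci <- auc_with_ci(scores, labels)
    ci$ci_low <= 0.5 && 0.5 <= ci$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.90)
})

test_that("confusion metrics satisfy their identities with Wilson intervals", {
  # fixture realizing TP=2, FP=1, TN=2, FN=1 at cutoff 0.5
  scores <- c(0.9, 0.8, 0.6, 0.4, 0.3, 0.2)
  labels <- c(1, 1, 0, 1, 0, 0)
  m <- confusion_metrics_at_cutoff(scores, labels, 0.5)
  expect_equal(unname(m$counts), c(2L, 1L, 2L, 1L))
  expect_equal(m$sensitivity$estimate, 2 / 3)
  expect_equal(m$specificity$estimate, 2 / 3)
  expect_equal(m$ppv$estimate, 2 / 3)
  expect_equal(m$npv$estimate, 2 / 3)
  expect_equal(sum(m$counts), 6)
  expect_true(m$sensitivity$ci_low <= m$sensitivity$estimate &&
              m$sensitivity$estimate <= m$sensitivity$ci_high)

  lo <- confusion_metrics_at_cutoff(scores, labels, -1)
  expect_equal(lo$sensitivity$estimate, 1)
  expect_equal(lo$specificity$estimate, 0)
  expect_true(lo$npv$undefined)

  hi <- confusion_metrics_at_cutoff(scores, labels, 2)
  expect_equal(hi$sensitivity$estimate, 0)
  expect_equal(hi$specificity$estimate, 1)
  expect_true(hi$ppv$undefined)
  expect_true(is.na(hi$ppv$estimate))
})

test_that("Wilson intervals reach nominal coverage on simulated binomials", {
  set.seed(606)
  p <- 0.3; n <- 100
  hits <- vapply(1:1000, function(i) {
    x <- rbinom(1, n, p)
    ci <- wilson_ci(x, n)
    ci[1] <= p && p <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("subgroup evaluation partitions the validation set and flags degenerate groups", {
  v <- small_cohort(6000L, seed = 61L)
  sp <- split_train_validation(v, 0.8, 1L)
  tab <- fit_cc_risk_table(sp$train)
  x <- encode_features(sp$train, tab)
  m <- train_admission_model(x, admission_labels(sp$train),
                             training_config(max_epochs = 8L, seed = 1L))
  rep <- evaluate_subgroups(m, sp$validation, tab)
  expect_setequal(names(rep), c("all", cc_categories()))
  expect_equal(sum(vapply(rep[cc_categories()], `[[`, 0L, "n")),
               rep$all$n)
  # union-consistency: pooled subgroup scores reproduce the all-patient AUC
  xv <- encode_features(sp$validation, tab)
  scores <- predict_admission_probability(m, xv)
  expect_equal(rep$all$auc$auc,
               auc_with_ci(scores, admission_labels(sp$validation))$auc)
  # env_emergency at this n has almost no admissions: degenerate flag, no AUC
  degen <- rep$env_emergency
  if (degen$degenerate) expect_null(degen$auc)

  # a category with zero admitted patients is flagged, not an error
  v2 <- sp$validation
  v2$disposition[v2$cc_category == "trauma"] <- "discharge"
  v2$hospital_outcome[v2$cc_category == "trauma"] <- "not_hospitalized"
  rep2 <- evaluate_subgroups(m, v2, tab)
  expect_true(rep2$trauma$degenerate)
  expect_error(evaluate_subgroups(m, sp$validation[0, ], tab), "empty")
})
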
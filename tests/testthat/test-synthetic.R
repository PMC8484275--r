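test_that("generation is seed-deterministic and size-exact", {
  cfg <- default_cohort_config(n_visits = 500L, seed = 17L)
  v1 <- generate_cohort(cfg)
  v2 <- generate_cohort(cfg)
  expect_identical(v1, v2)
  expect_equal(nrow(v1), 500L)
  one <- generate_cohort(default_cohort_config(n_visits = 1L, seed = 4L))
  expect_identical(one,
                   generate_cohort(default_cohort_config(n_visits = 1L,
                                                         seed = 4L)))
  expect_error(generate_cohort(default_cohort_config(n_visits = 0L)),
               "n_visits")
})

test_that("invalid config fields are rejected by name", {
  cfg <- default_cohort_config(n_visits = 10L)
  cfg$admission_rate <- 1.4
  expect_error(generate_cohort(cfg), "admission_rate")
  cfg2 <- default_cohort_config(n_visits = 10L)
  cfg2$cc_catalogue$mortality[1] <- 2
  expect_error(generate_cohort(cfg2), "cc_catalogue")
  cfg3 <- default_cohort_config(n_visits = 10L)
  cfg3$rate_missing_fields <- -0.1
  expect_error(generate_cohort(cfg3), "rate_missing_fields")
})

test_that("default config targets the published cohort composition", {
  cfg <- default_cohort_config()
  expect_equal(cfg$admission_rate, 0.1576)
  # marginal category mix implied by the per-disposition compositions
  admitted_mix <- c(nontraumatic_adult = 0.7732, pediatrics = 0.1325,
                    trauma = 0.0933, env_emergency = 0.0010)
  discharged_mix <- c(nontraumatic_adult = 0.6451, pediatrics = 0.2034,
                      trauma = 0.1470, env_emergency = 0.0044)
  marginal <- cfg$admission_rate * admitted_mix +
    (1 - cfg$admission_rate) * discharged_mix
  expect_equal(unname(marginal[c("nontraumatic_adult", "pediatrics",
                                 "trauma", "env_emergency")]),
               c(0.6653, 0.1923, 0.1386, 0.0039), tolerance = 0.002)
  expect_equal(unname(cfg$vital_means["discharge", 1]), 37.04)
  expect_equal(unname(cfg$vital_means["admit", 1]), 37.24)
})

test_that("empirical marginals recover configured probabilities within 3 SE", {
  n <- 50000L
  v <- generate_cohort(default_cohort_config(n_visits = n, seed = 19L))
  p_adm <- 0.1576
  se <- sqrt(p_adm * (1 - p_adm) / n)
  expect_lt(abs(mean(v$disposition == "admit") - p_adm), 3 * se)
  target_mix <- c(nontraumatic_adult = 0.6653, pediatrics = 0.1923,
                  trauma = 0.1386, env_emergency = 0.0039)
  emp <- prop.table(table(v$cc_category))
  for (g in names(target_mix)) {
    se_g <- sqrt(target_mix[g] * (1 - target_mix[g]) / n)
    expect_lt(abs(emp[[g]] - target_mix[g]), 3 * se_g + 0.002)
  }
})

test_that("generated records respect physiologic and structural invariants", {
  v <- generate_cohort(default_cohort_config(n_visits = 20000L, seed = 23L))
  expect_true(all(v$diastolic_bp <= v$mean_arterial_pressure))
  expect_true(all(v$mean_arterial_pressure <= v$systolic_bp))
  expect_true(all(v$medical_history_score >= 0 & v$medical_history_score <= 12))
  expect_true(all(v$triage_level == 3))
  adm <- v$disposition == "admit"
  expect_true(all(v$hospital_outcome[!adm] == "not_hospitalized"))
  expect_true(all(v$hospital_outcome[adm] %in% c("recovered", "deceased")))
  expect_true(all((v$cc_category == "pediatrics") == FALSE |
                    v$age < 18))
})

test_that("per-disposition means land on the published descriptive table", {
  v <- generate_cohort(default_cohort_config(n_visits = 50000L, seed = 29L))
  adm <- v$disposition == "admit"
  cm <- function(f) c(mean(v[[f]][!adm]), mean(v[[f]][adm]))
  expect_equal(cm("age"), c(39.5, 55.05), tolerance = 0.02)
  expect_equal(cm("temperature"), c(37.04, 37.24), tolerance = 0.002)
  expect_equal(cm("heart_rate"), c(96.74, 98.39), tolerance = 0.01)
  expect_equal(cm("respiratory_rate"), c(19.86, 19.73), tolerance = 0.01)
  expect_equal(cm("systolic_bp"), c(133.72, 135.32), tolerance = 0.01)
  expect_equal(cm("diastolic_bp"), c(82.59, 80.63), tolerance = 0.01)
  expect_equal(cm("medical_history_score"), c(0.2619, 0.8781),
               tolerance = 0.05)
  expect_equal(c(mean(v$sex[!adm]), mean(v$sex[adm])), c(0.4747, 0.5297),
               tolerance = 0.02)
})

test_that("raw stream with zero corruption rates passes the filters unchanged", {
  cfg <- default_cohort_config(n_visits = 800L, seed = 31L)
  cfg$rate_missing_fields <- 0
  cfg$rate_non_standard_disposition <- 0
  cfg$rate_other_level <- 0
  raw <- generate_raw_stream(cfg)
  res <- apply_inclusion_filters(raw)
  expect_equal(res$tally$n_retained, 800L)
  expect_identical(res$visits, raw)
})

test_that("raw-stream retention matches the joint survival probability", {
  cfg <- default_cohort_config(n_visits = 10000L, seed = 37L)
  cfg$rate_missing_fields <- 0.1
  cfg$rate_non_standard_disposition <- 0.05
  cfg$rate_other_level <- 0.2
  raw <- generate_raw_stream(cfg)
  expect_identical(raw, generate_raw_stream(cfg))  # determinism
  res <- apply_inclusion_filters(raw)
  p_keep <- (1 - 0.1) * (1 - 0.05) * (1 - 0.2)
  se <- sqrt(p_keep * (1 - p_keep) / 10000)
  expect_lt(abs(res$tally$n_retained / 10000 - p_keep), 3 * se)
})

test_that("the true posterior logit is the Bayes-optimal score (upper bounds the model)", {
  cfg <- default_cohort_config(n_visits = 30000L, seed = 41L)
  v <- generate_cohort(cfg)
  sp <- split_train_validation(v, 0.8, 1L)
  eta <- true_admission_logit(sp$validation, cfg)
  y <- admission_labels(sp$validation)
  bayes <- auc_with_ci(eta, y)
  tab <- fit_cc_risk_table(sp$train)
  x <- encode_features(sp$train, tab)
  m <- train_admission_model(x, admission_labels(sp$train),
                             training_config(max_epochs = 25L, seed = 1L))
  p <- predict_admission_probability(m,
                                     encode_features(sp$validation, tab))
  trained <- auc_with_ci(p, y)
  expect_lte(trained$auc, bayes$auc + 0.01)
  # and the trained model is far above chance
  expect_gt(trained$auc, 0.7)
})

test_that("the shipped example config loads and generates", {
  path <- system.file("extdata", "cohort_config_example.yaml",
                      package = "edtriage")
  cfg <- read_cohort_config(path)
  cfg$n_visits <- 50L
  v <- generate_cohort(cfg)
  expect_equal(nrow(v), 50L)
})

test_that("cohort config round-trips through YAML", {
  cfg <- default_cohort_config(n_visits = 123L, seed = 9L)
  path <- tempfile(fileext = ".yaml")
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_equal(back$n_visits, cfg$n_visits)
  expect_equal(back$admission_rate, cfg$admission_rate)
  expect_equal(back$vital_means, cfg$vital_means)
  expect_equal(back$age_band_probs, cfg$age_band_probs)
  expect_equal(back$cc_catalogue$enrichment, cfg$cc_catalogue$enrichment)
  expect_equal(back$map_noise$probs, cfg$map_noise$probs)
  expect_identical(generate_cohort(back), generate_cohort(cfg))
})
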
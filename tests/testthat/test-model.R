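# independent per-layer count: enumerate each tensor's dimensions by hand
layerwise_count <- function(d, h1 = 100L, h2 = 12L) {
  dense1 <- d * h1 + h1
  bn1 <- h1 + h1
  dense2 <- h1 * h2 + h2
  bn2 <- h2 + h2
  dense3 <- h2 * 1L + 1L
  dense1 + bn1 + dense2 + bn2 + dense3
}

test_that("the ten-input model has exactly 2549 trainable parameters", {
  expect_equal(count_trainable_parameters(nn_architecture(10L)), 2549L)
  expect_equal(count_trainable_parameters(nn_architecture(1L)), 1649L)
  expect_equal(count_trainable_parameters(nn_architecture(6L)), 2149L)
})

test_that("parameter closed form 100d + 1549 matches layerwise counting for d in 1..20", {
  for (d in 1:20) {
    arch <- nn_architecture(d)
    expect_equal(count_trainable_parameters(arch), 100L * d + 1549L)
    expect_equal(count_trainable_parameters(arch), layerwise_count(d))
  }
  expect_error(nn_architecture(0L), "positive integer")
})

test_that("the stored weight tensors realize the counted parameters", {
  set.seed(501)
  x <- matrix(rnorm(300), 150, 2)
  y <- rbinom(150, 1, 0.5)
  m <- train_admission_model(x, y, training_config(max_epochs = 2L, seed = 1L))
  w <- m$weights
  trained <- sum(length(w$W1), length(w$b1), length(w$gamma1),
                 length(w$beta1), length(w$W2), length(w$b2),
                 length(w$gamma2), length(w$beta2), length(w$W3),
                 length(w$b3))
  expect_equal(trained, count_trainable_parameters(m))
  expect_equal(trained, 100L * 2L + 1549L)
})

test_that("a linearly separable toy problem is learned to >= 99% training accuracy", {
  set.seed(502)
  n <- 200
  x <- cbind(c(runif(n / 2, -3, -0.5), runif(n / 2, 0.5, 3)), rnorm(n))
  y <- rep(c(0, 1), each = n / 2)
  m <- train_admission_model(x, y, training_config(batch_size = 32L,
                                                   max_epochs = 60L,
                                                   patience = 60L,
                                                   seed = 3L))
  p <- predict_admission_probability(m, x)
  expect_gte(mean((p >= 0.5) == (y == 1)), 0.99)
})

test_that("training is seed-deterministic and seeds matter", {
  v <- small_cohort(1500L, seed = 51L)
  tab <- fit_cc_risk_table(v)
  x <- encode_features(v, tab)
  y <- admission_labels(v)
  cfg <- training_config(max_epochs = 5L, seed = 9L)
  m1 <- train_admission_model(x, y, cfg)
  m2 <- train_admission_model(x, y, cfg)
  expect_identical(predict_admission_probability(m1, x),
                   predict_admission_probability(m2, x))
  cfg2 <- cfg; cfg2$seed <- 10L
  m3 <- train_admission_model(x, y, cfg2)
  expect_false(identical(predict_admission_probability(m1, x),
                         predict_admission_probability(m3, x)))
})

test_that("permuted labels yield chance-level validation AUC", {
  set.seed(503)
  v <- small_cohort(4000L, seed = 52L)
  tab <- fit_cc_risk_table(v)
  x <- encode_features(v, tab)
  y <- sample(admission_labels(v))       # break the label-feature link
  half <- seq_len(2000)
  m <- train_admission_model(x[half, ], y[half],
                             training_config(max_epochs = 20L, seed = 1L))
  p <- predict_admission_probability(m, x[-half, ])
  au <- auc_with_ci(p, y[-half])
  expect_lt(abs(au$auc - 0.5), 0.05)
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(rnorm(40), 20, 2)
  expect_error(train_admission_model(x, rep(1, 20)), "both classes")
  x2 <- x; x2[3, 1] <- NaN
  expect_error(train_admission_model(x2, rep(c(0, 1), 10)), "non-finite")
  expect_error(train_admission_model(x, rep(c(0, 1), 10) + 0.5), "binary")
})

test_that("inference is batch-independent and strictly inside (0,1)", {
  set.seed(504)
  x <- matrix(rnorm(500), 100, 5)
  y <- rbinom(100, 1, 0.4)
  m <- train_admission_model(x, y, training_config(max_epochs = 3L,
                                                   batch_size = 32L,
                                                   seed = 2L))
  p_batch <- predict_admission_probability(m, x)
  p_single <- vapply(seq_len(20), function(i)
    predict_admission_probability(m, x[i, , drop = FALSE]), numeric(1))
  # row-wise independence is exact up to BLAS summation order
  expect_equal(p_single, p_batch[1:20], tolerance = 1e-12)
  expect_true(all(p_batch > 0 & p_batch < 1))
  expect_error(predict_admission_probability(m, x[, 1:3]), "columns")
})

test_that("a one-feature model trained on monotone data responds monotonically", {
  set.seed(505)
  n <- 1500
  x <- matrix(runif(n, 0, 2), n, 1)
  y <- rbinom(n, 1, plogis(3 * (x[, 1] - 1)))
  m <- train_admission_model(x, y, training_config(max_epochs = 30L, seed = 4L))
  grid <- matrix(seq(0.05, 1.95, length.out = 100), ncol = 1)
  p <- predict_admission_probability(m, grid)
  expect_gt(cor(grid[, 1], p, method = "spearman"), 0.95)
})

test_that("save/load round-trips predictions bit-exactly", {
  v <- small_cohort(1200L, seed = 53L)
  tab <- fit_cc_risk_table(v)
  x <- encode_features(v, tab)
  m <- train_admission_model(x, admission_labels(v),
                             training_config(max_epochs = 4L, seed = 6L))
  dir <- tempfile("model")
  save_model(m, dir)
  m2 <- load_model(dir)
  expect_identical(predict_admission_probability(m2, x),
                   predict_admission_probability(m, x))
  expect_equal(m2$feature_subset, m$feature_subset)
  expect_equal(m2$config$seed, m$config$seed)
  expect_equal(m2$fit$best_epoch, m$fit$best_epoch)
})

test_that("training loss improves over the best-epoch trajectory", {
  v <- small_cohort(2000L, seed = 54L)
  tab <- fit_cc_risk_table(v)
  x <- encode_features(v, tab)
  m <- train_admission_model(x, admission_labels(v),
                             training_config(max_epochs = 15L, seed = 7L))
  tl <- m$fit$train_loss
  expect_lt(tl[m$fit$epochs_run], tl[1])
  # the monitor loss at the selected epoch is the minimum seen
  expect_equal(m$fit$best_monitor_loss, min(m$fit$monitor_loss))
})
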
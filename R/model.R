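#' Architecture of the admission classifier
#'
#' The classifier is a three-layer feedforward network with layer output
#' dimensions 100, 12 and 1, batch normalization between layers (after
#' each of the first two dense layers, before the rectifier), and a
#' sigmoid on the output so predictions are admission probabilities in
#' (0, 1). For input dimension `d` the trainable parameter count is
#' `100 d + 1549`: dense layers contribute `100 d + 100`, `100*12 + 12`
#' and `12 + 1` (weights + biases) and each batch-norm layer contributes a
#' scale and shift per unit (`2*100` and `2*12`); running statistics are
#' not trained. The ten-variable model therefore has exactly 2549
#' trainable parameters.
#'
#' @param input_dim Number of input variables, a positive integer.
#' @param hidden_dims Output dimensions of the two hidden layers
#'   (default `c(100, 12)`).
#' @return An `nn_architecture` object.
#' @export
nn_architecture <- function(input_dim, hidden_dims = c(100L, 12L)) {
  if (!is.numeric(input_dim) || length(input_dim) != 1L ||
      is.na(input_dim) || input_dim < 1 || input_dim != round(input_dim)) {
    stop("'input_dim' must be a positive integer")
  }
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 batch_norm = TRUE,
                 hidden_activation = "relu",
                 output_activation = "sigmoid"),
            class = "nn_architecture")
}

#' @export
print.nn_architecture <- function(x, ...) {
  cat(sprintf(
    "Feedforward classifier: %d -> %s -> 1 (batch-norm + %s; %s output)\n",
    x$input_dim, paste(x$hidden_dims, collapse = " -> "),
    x$hidden_activation, x$output_activation))
  cat("Trainable parameters:", count_trainable_parameters(x), "\n")
  invisible(x)
}

#' Count trainable parameters
#'
#' Counts dense weights, biases, and batch-norm scale/shift pairs;
#' batch-norm running statistics are buffers, not parameters. For the
#' default hidden dimensions this is `100 * input_dim + 1549`, and the
#' count depends only on the architecture, never on training.
#'
#' @param model An `nn_architecture` or a trained `admission_model`.
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(model) {
  if (inherits(model, "admission_model")) model <- model$architecture
  stopifnot(inherits(model, "nn_architecture"))
  d <- model$input_dim
  h <- model$hidden_dims
  dense <- d * h[1] + h[1] + h[1] * h[2] + h[2] + h[2] + 1L
  bn <- if (model$batch_norm) 2L * h[1] + 2L * h[2] else 0L
  as.integer(dense + bn)
}

#' Training configuration
#'
#' Hyperparameters of the fit. Defaults: Adam with learning rate 1e-3,
#' batch size 512, at most 100 epochs, early stopping with patience 10 on
#' a 10% monitor slice carved out of the training set, all randomness
#' fixed by `seed`. Every trained model carries its configuration.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of passes over the data.
#' @param patience Epochs without monitor-loss improvement before stopping.
#' @param monitor_fraction Fraction of the training rows held out to drive
#'   early stopping (never the validation set).
#' @param seed Integer seed fixing initialization, shuffles and the
#'   monitor slice.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-3, batch_size = 512L,
                            max_epochs = 100L, patience = 10L,
                            monitor_fraction = 0.1, seed = 1L) {
  structure(list(optimizer = "adam",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 monitor_fraction = monitor_fraction,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Train the admission classifier
#'
#' Fits the batch-normalized network by minibatch Adam on binary
#' cross-entropy, with early stopping on a monitor slice of the training
#' rows; the weights returned are those of the best monitor epoch.
#' Training is deterministic given `config$seed` and the data.
#'
#' @param features Numeric matrix, one row per visit (see
#'   [encode_features()]).
#' @param labels Binary vector (admission 1 / discharge 0) with both
#'   classes present.
#' @param config A [training_config()].
#' @param feature_names Optional character vector naming the columns;
#'   defaults to `colnames(features)`.
#' @return An `admission_model`: architecture, weights, config, feature
#'   subset and fit metadata (epochs run, best epoch, loss history).
#' @export
train_admission_model <- function(features, labels,
                                  config = training_config(),
                                  feature_names = colnames(features)) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (anyNA(features) || any(!is.finite(features))) {
    stop("data integrity: non-finite values in the feature matrix")
  }
  labels <- as.numeric(labels)
  if (nrow(features) != length(labels) || nrow(features) < 2L) {
    stop("features and labels must have the same length (>= 2)")
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present in the labels")
  }
  arch <- nn_architecture(ncol(features))
  fit <- nn_train_cpp(features, labels,
                      arch$hidden_dims[1], arch$hidden_dims[2],
                      config$learning_rate, config$batch_size,
                      config$max_epochs, config$patience,
                      config$monitor_fraction, as.double(config$seed))
  weights <- fit[c("W1", "b1", "gamma1", "beta1",
                   "running_mean1", "running_var1",
                   "W2", "b2", "gamma2", "beta2",
                   "running_mean2", "running_var2", "W3", "b3")]
  structure(list(architecture = arch,
                 weights = weights,
                 config = config,
                 feature_subset = feature_names,
                 fit = list(epochs_run = fit$epochs_run,
                            best_epoch = fit$best_epoch,
                            train_loss = fit$train_loss,
                            monitor_loss = fit$monitor_loss,
                            best_monitor_loss = fit$best_monitor_loss)),
            class = "admission_model")
}

#' @export
print.admission_model <- function(x, ...) {
  cat(sprintf(
    "Admission classifier on %d variable(s): %s\n", x$architecture$input_dim,
    paste(x$feature_subset, collapse = ", ")))
  cat(sprintf("  %d trainable parameters; trained %d epoch(s), best epoch %d (seed %d)\n",
              count_trainable_parameters(x), x$fit$epochs_run,
              x$fit$best_epoch, x$config$seed))
  invisible(x)
}

#' Predict admission probabilities
#'
#' Applies the trained network in inference mode: batch normalization uses
#' the stored running statistics, so each row's prediction is independent
#' of what other rows are in the batch. Outputs are clamped to the open
#' interval (0, 1). Implemented as plain matrix arithmetic in R,
#' independently of the C++ training-time forward pass.
#'
#' @param model An `admission_model`.
#' @param features Numeric matrix whose column count matches the model's
#'   feature subset.
#' @return Numeric vector of admission probabilities, one per row.
#' @export
predict_admission_probability <- function(model, features) {
  stopifnot(inherits(model, "admission_model"))
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (ncol(features) != model$architecture$input_dim) {
    stop(sprintf("feature matrix has %d columns; model expects %d",
                 ncol(features), model$architecture$input_dim))
  }
  w <- model$weights
  eps <- 1e-5
  a1 <- sweep(features %*% w$W1, 2, w$b1, `+`)
  a1 <- sweep(sweep(a1, 2, w$running_mean1, `-`), 2,
              w$gamma1 / sqrt(w$running_var1 + eps), `*`)
  a1 <- pmax(sweep(a1, 2, w$beta1, `+`), 0)
  a2 <- sweep(a1 %*% w$W2, 2, w$b2, `+`)
  a2 <- sweep(sweep(a2, 2, w$running_mean2, `-`), 2,
              w$gamma2 / sqrt(w$running_var2 + eps), `*`)
  a2 <- pmax(sweep(a2, 2, w$beta2, `+`), 0)
  f <- drop(a2 %*% w$W3) + w$b3
  p <- 1 / (1 + exp(-f))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' @rdname predict_admission_probability
#' @param object,newdata,... standard `predict` interface; `newdata` is
#'   the feature matrix.
#' @export
predict.admission_model <- function(object, newdata, ...) {
  predict_admission_probability(object, newdata)
}

#' Persist a trained model
#'
#' Writes a model as a directory of plain-text files: `config.yaml`
#' (architecture, training configuration, feature subset, fit metadata)
#' and `weights.csv` with each value printed at 17 significant digits so
#' doubles round-trip bit-exactly; [load_model()] reproduces predictions
#' identically.
#'
#' @param model An `admission_model`.
#' @param dir Directory to create/write.
#' @return `dir`, invisibly.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "admission_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    architecture = unclass(model$architecture),
    training_config = unclass(model$config),
    feature_subset = model$feature_subset,
    fit = model$fit[c("epochs_run", "best_epoch", "best_monitor_loss")])
  yaml::write_yaml(meta, file.path(dir, "config.yaml"))
  rows <- do.call(rbind, lapply(names(model$weights), function(nm) {
    v <- model$weights[[nm]]
    data.frame(tensor = nm,
               nrow = if (is.matrix(v)) nrow(v) else length(v),
               ncol = if (is.matrix(v)) ncol(v) else 1L,
               index = seq_along(v),
               value = sprintf("%.17g", as.vector(v)),
               stringsAsFactors = FALSE)
  }))
  write.csv(rows, file.path(dir, "weights.csv"), row.names = FALSE,
            quote = FALSE)
  losses <- data.frame(epoch = seq_along(model$fit$train_loss),
                       train_loss = model$fit$train_loss,
                       monitor_loss = model$fit$monitor_loss)
  write.csv(losses, file.path(dir, "loss_history.csv"), row.names = FALSE)
  invisible(dir)
}

#' Load a persisted model
#'
#' @param dir Directory written by [save_model()].
#' @return The reconstructed `admission_model`.
#' @export
load_model <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "config.yaml"))
  rows <- read.csv(file.path(dir, "weights.csv"),
                   colClasses = c("character", "integer", "integer",
                                  "integer", "character"))
  weights <- lapply(split(rows, factor(rows$tensor, levels = unique(rows$tensor))),
                    function(df) {
                      v <- as.numeric(df$value[order(df$index)])
                      if (df$ncol[1] > 1L || df$tensor[1] %in% c("W1", "W2", "W3")) {
                        matrix(v, nrow = df$nrow[1], ncol = df$ncol[1])
                      } else if (df$tensor[1] == "b3") v else v
                    })
  hist_path <- file.path(dir, "loss_history.csv")
  losses <- if (file.exists(hist_path)) read.csv(hist_path) else NULL
  arch <- do.call(nn_architecture,
                  meta$architecture[c("input_dim", "hidden_dims")])
  cfg <- do.call(training_config,
                 meta$training_config[c("learning_rate", "batch_size",
                                        "max_epochs", "patience",
                                        "monitor_fraction", "seed")])
  structure(list(architecture = arch,
                 weights = weights[c("W1", "b1", "gamma1", "beta1",
                                     "running_mean1", "running_var1",
                                     "W2", "b2", "gamma2", "beta2",
                                     "running_mean2", "running_var2",
                                     "W3", "b3")],
                 config = cfg,
                 feature_subset = unlist(meta$feature_subset),
                 fit = list(epochs_run = meta$fit$epochs_run,
                            best_epoch = meta$fit$best_epoch,
                            train_loss = losses$train_loss,
                            monitor_loss = losses$monitor_loss,
                            best_monitor_loss = meta$fit$best_monitor_loss)),
            class = "admission_model")
}
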
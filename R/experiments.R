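#' Train and evaluate one pipeline condition
#'
#' Internal worker shared by the main run, learning curve and ablation:
#' refits the chief-complaint risk table on the given training rows,
#' encodes the variable subset, trains the network and evaluates on the
#' common validation set. The risk table is always refit on exactly the
#' rows being trained on, so no statistic of held-out data leaks into the
#' encoder.
#' @noRd
.fit_and_evaluate <- function(train, validation, subset, config) {
  table <- fit_cc_risk_table(train)
  x_tr <- encode_features(train, table, subset)
  x_va <- encode_features(validation, table, subset)
  model <- train_admission_model(x_tr, admission_labels(train), config)
  scores <- predict_admission_probability(model, x_va)
  list(model = model, table = table, scores = scores,
       report = evaluate_predictions(scores, admission_labels(validation)))
}

#' Training-fraction learning curve
#'
#' Retrains the full pipeline (risk-table refit + network) on nested
#' random subsamples of the training set — 100%, 75%, 50%, 25% and 12.5%
#' by default — and reports the validation AUC with CI for each fraction
#' on the one fixed validation set. Subsamples are nested per seed
#' (each smaller fraction is a prefix of the same shuffled order), which
#' reduces between-fraction sampling variance. A fraction of exactly 1
#' uses the training set as-is, so under the same training seed it
#' reproduces the main-run model exactly. Conditions with fewer than 100
#' records are skipped with a recorded reason.
#'
#' @param train,validation Post-filter visit data frames.
#' @param fractions Training fractions in (0, 1].
#' @param seeds Integer vector of replicate seeds; seed `i` controls both
#'   the subsample shuffle and the training seed of its replicate.
#' @param subset Variable subset (default all ten).
#' @param config Base [training_config()]; its seed is replaced per
#'   replicate.
#' @param full_model Optional pretrained model for the (fraction 1,
#'   first seed) condition, to avoid retraining the main model; it must
#'   have been trained with the same configuration.
#' @return An `experiment_report` data frame: one row per (fraction,
#'   seed) with `n_train`, `auc`, `ci_low`, `ci_high`, `skipped`.
#' @export
learning_curve <- function(train, validation,
                           fractions = c(1, 0.75, 0.5, 0.25, 0.125),
                           seeds = 1:3, subset = canonical_features(),
                           config = training_config(),
                           full_model = NULL) {
  stopifnot(all(fractions > 0 & fractions <= 1))
  fractions <- sort(fractions, decreasing = TRUE)
  n <- nrow(train)
  y_va <- admission_labels(validation)
  rows <- list()
  for (s in seeds) {
    old <- .save_rng_state()
    set.seed(as.integer(s))
    shuffle <- sample.int(n)
    .restore_rng_state(old)
    cfg <- config
    cfg$seed <- as.integer(s)
    for (f in fractions) {
      k <- as.integer(round(f * n))
      if (k < 100L) {
        rows[[length(rows) + 1L]] <- data.frame(
          fraction = f, seed = s, n_train = k, auc = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, skipped = TRUE,
          reason = "fewer than 100 training records")
        message(sprintf("learning_curve: skipping fraction %.3g (n=%d < 100)",
                        f, k))
        next
      }
      sub_train <- if (f == 1) train else train[shuffle[seq_len(k)], , drop = FALSE]
      if (f == 1 && s == seeds[1] && !is.null(full_model)) {
        table <- fit_cc_risk_table(sub_train)
        x_va <- encode_features(validation, table, subset)
        scores <- predict_admission_probability(full_model, x_va)
        au <- auc_with_ci(scores, y_va)
      } else {
        fit <- .fit_and_evaluate(sub_train, validation, subset, cfg)
        au <- fit$report$auc
      }
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, seed = s, n_train = k, auc = au$auc,
        ci_low = au$ci_low, ci_high = au$ci_high, skipped = FALSE,
        reason = "")
    }
  }
  structure(do.call(rbind, rows),
            class = c("experiment_report", "data.frame"),
            experiment = "learning_curve")
}

#' Variable-ablation experiment
#'
#' Trains one model per variable subset (each with its own input
#' dimension, hence `100 d + 1549` trainable parameters) on the full
#' training set and compares validation AUCs. The default subsets are the
#' four of the ablation design: all ten variables; nine (no chief
#' complaint); the six-variable core (age, sex, heart rate, MAP, medical
#' history, chief complaint); and the core without the chief complaint
#' (five).
#'
#' @param train,validation Post-filter visit data frames.
#' @param subsets Named list of variable subsets (default
#'   [ablation_subsets()]).
#' @param seeds Replicate training seeds.
#' @param config Base [training_config()].
#' @return An `experiment_report` data frame: one row per (subset, seed)
#'   with `n_features`, `n_parameters`, `auc`, `ci_low`, `ci_high`.
#' @export
ablation_study <- function(train, validation, subsets = ablation_subsets(),
                           seeds = 1L, config = training_config()) {
  rows <- list()
  for (s in seeds) {
    cfg <- config
    cfg$seed <- as.integer(s)
    for (nm in names(subsets)) {
      subset <- subsets[[nm]]
      fit <- .fit_and_evaluate(train, validation, subset, cfg)
      au <- fit$report$auc
      rows[[length(rows) + 1L]] <- data.frame(
        subset = nm, seed = s, n_features = length(subset),
        n_parameters = count_trainable_parameters(fit$model),
        auc = au$auc, ci_low = au$ci_low, ci_high = au$ci_high)
    }
  }
  structure(do.call(rbind, rows),
            class = c("experiment_report", "data.frame"),
            experiment = "ablation")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment report (", attr(x, "experiment"), "):\n", sep = "")
  print.data.frame(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Experiment plan
#'
#' Bundles every knob of a full analysis run: the cohort configuration,
#' split fraction and seed, training configuration, learning-curve
#' fractions, ablation subsets and replicate seeds.
#'
#' @param cohort_config A [default_cohort_config()]-style configuration.
#' @param split_fraction Training fraction of the random split.
#' @param split_seed Seed of the split.
#' @param training_config A [training_config()].
#' @param fractions Learning-curve fractions.
#' @param subsets Ablation subsets.
#' @param replicate_seeds Seeds for learning-curve replicates.
#' @return An `experiment_plan` list.
#' @export
experiment_plan <- function(cohort_config = default_cohort_config(),
                            split_fraction = 0.8, split_seed = 1L,
                            training_config = edtriage::training_config(),
                            fractions = c(1, 0.75, 0.5, 0.25, 0.125),
                            subsets = ablation_subsets(),
                            replicate_seeds = 1:3) {
  structure(list(cohort_config = cohort_config,
                 split_fraction = split_fraction,
                 split_seed = as.integer(split_seed),
                 training_config = training_config,
                 fractions = fractions,
                 subsets = subsets,
                 replicate_seeds = as.integer(replicate_seeds)),
            class = "experiment_plan")
}

#' Run the full analysis pipeline
#'
#' Executes the end-to-end study on a synthetic cohort: generate a raw
#' stream, apply the inclusion filters, split train/validation, check
#' split similarity, fit the chief-complaint encoder, train the
#' ten-variable model, evaluate overall and per subgroup, then run the
#' learning-curve and ablation experiments against the same validation
#' set. The validation rows are identical across every condition, and the
#' learning curve's 100% condition reuses the main model (no hidden
#' retraining). Given the same plan the run is fully reproducible; when
#' `out_dir` is given, all artifacts (visits CSV, risk table, model
#' directory, report JSON/CSVs, ROC plot) are persisted there.
#'
#' @param plan An [experiment_plan()].
#' @param out_dir Optional run directory.
#' @param verbose Print stage progress.
#' @return A `full_analysis` list: `tally`, `split` sizes, `similarity`,
#'   `risk_table`, `model`, `evaluation`, `subgroups`, `learning_curve`,
#'   `ablation`.
#' @export
run_full_analysis <- function(plan = experiment_plan(), out_dir = NULL,
                              verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "generate"
  result <- tryCatch({
    say("[generate] %d raw visits (seed %d)",
        plan$cohort_config$n_visits, plan$cohort_config$seed)
    raw <- generate_raw_stream(plan$cohort_config)

    stage <- "filter"
    filt <- apply_inclusion_filters(raw)
    say("[filter] retained %d / %d", filt$tally$n_retained, filt$tally$n_input)

    stage <- "split"
    split <- split_train_validation(filt$visits, plan$split_fraction,
                                    plan$split_seed)
    say("[split] %d train / %d validation", nrow(split$train),
        nrow(split$validation))

    stage <- "similarity"
    sim <- similarity_report(split$train, split$validation)

    stage <- "encode+train"
    main <- .fit_and_evaluate(split$train, split$validation,
                              canonical_features(), plan$training_config)
    say("[train] main model: %d epochs, validation AUC %.4f",
        main$model$fit$epochs_run, main$report$auc$auc)

    stage <- "subgroups"
    sub <- evaluate_subgroups(main$model, split$validation, main$table)

    stage <- "learning_curve"
    lc <- learning_curve(split$train, split$validation, plan$fractions,
                         plan$replicate_seeds,
                         config = plan$training_config,
                         full_model = if (plan$replicate_seeds[1] ==
                                          plan$training_config$seed)
                           main$model else NULL)

    stage <- "ablation"
    ab <- ablation_study(split$train, split$validation, plan$subsets,
                         seeds = plan$training_config$seed,
                         config = plan$training_config)

    structure(list(plan = plan, tally = filt$tally,
                   n_train = nrow(split$train),
                   n_validation = nrow(split$validation),
                   similarity = sim, risk_table = main$table,
                   model = main$model, evaluation = main$report,
                   subgroups = sub, learning_curve = lc, ablation = ab,
                   split = split),
              class = "full_analysis")
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.null(out_dir)) write_run_artifacts(result, out_dir)
  result
}

#' @export
print.full_analysis <- function(x, ...) {
  cat("Full analysis run\n")
  print(x$tally)
  cat(sprintf("Split: %d train / %d validation\n", x$n_train, x$n_validation))
  print(x$evaluation)
  print(x$subgroups)
  print(x$learning_curve)
  print(x$ablation)
  invisible(x)
}

#' Serialize a full run to a directory
#'
#' Writes the exclusion tally and report as JSON, the similarity,
#' learning-curve, ablation and ROC tables as CSV, the risk table, the
#' model directory and the five-panel ROC figure. The JSON report
#' contains no timestamps, so identical plans yield byte-identical
#' reports.
#'
#' @param result A `full_analysis`.
#' @param out_dir Directory to write into.
#' @return `out_dir`, invisibly.
#' @export
write_run_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- full_analysis_report(result)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(unclass(result$tally),
                       file.path(out_dir, "exclusion_tally.json"),
                       auto_unbox = TRUE)
  write.csv(result$similarity, file.path(out_dir, "similarity.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(result$learning_curve),
            file.path(out_dir, "learning_curve.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$ablation),
            file.path(out_dir, "ablation.csv"), row.names = FALSE)
  write_cc_risk_table(result$risk_table, file.path(out_dir, "cc_risk_table.csv"))
  save_model(result$model, file.path(out_dir, "model"))
  write_roc_csv(result$subgroups, file.path(out_dir, "roc_curves.csv"))
  plot_roc_panels(result$subgroups, file.path(out_dir, "roc_panels.pdf"))
  invisible(out_dir)
}

#' Structured report of a full run
#'
#' @param result A `full_analysis`.
#' @return A plain list (JSON-ready) of the run's headline numbers.
#' @export
full_analysis_report <- function(result) {
  metric <- function(m) list(estimate = m$estimate, ci_low = m$ci_low,
                             ci_high = m$ci_high, undefined = m$undefined)
  ev <- result$evaluation
  list(
    n_input = result$tally$n_input,
    n_retained = result$tally$n_retained,
    n_train = result$n_train,
    n_validation = result$n_validation,
    trainable_parameters = count_trainable_parameters(result$model),
    auc = ev$auc$auc, auc_ci_low = ev$auc$ci_low,
    auc_ci_high = ev$auc$ci_high,
    youden_cutoff = ev$cutoff, youden_J = ev$J,
    sensitivity = metric(ev$metrics$sensitivity),
    specificity = metric(ev$metrics$specificity),
    ppv = metric(ev$metrics$ppv),
    npv = metric(ev$metrics$npv),
    subgroups = lapply(result$subgroups, function(g) {
      if (g$degenerate) {
        list(n = g$n, degenerate = TRUE)
      } else {
        list(n = g$n, degenerate = FALSE, auc = g$auc$auc,
             ci_low = g$auc$ci_low, ci_high = g$auc$ci_high)
      }
    }),
    learning_curve = as.data.frame(result$learning_curve),
    ablation = as.data.frame(result$ablation))
}
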
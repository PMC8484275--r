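#' Apply the study inclusion filters
#'
#' Retains urgent (level-3) visits with complete triage information and a
#' standard disposition (admission or discharge). Each excluded record is
#' counted under exactly one reason, assessed in a fixed order:
#' `not_level3` (triage level recorded and not 3), then `missing_fields`
#' (any missing field, a missing triage level, or disposition recorded as
#' "missing"), then `non_standard_disposition` (transfer, against-advice
#' discharge, other).
#'
#' Filtering is idempotent: records that survive one pass survive any
#' further pass unchanged.
#'
#' @param visits Visit `data.frame` (see [visit_fields()]); fields may be
#'   missing.
#' @return A list with elements `visits` (the retained rows) and `tally`,
#'   an `exclusion_tally` with per-reason counts, `n_input` and
#'   `n_retained`.
#' @export
apply_inclusion_filters <- function(visits) {
  stopifnot(is.data.frame(visits))
  n <- nrow(visits)
  if (n == 0L) {
    tally <- structure(
      list(not_level3 = 0L, missing_fields = 0L,
           non_standard_disposition = 0L, n_input = 0L, n_retained = 0L),
      class = "exclusion_tally")
    return(list(visits = visits, tally = tally))
  }
  level <- visits$triage_level
  not_level3 <- !is.na(level) & level != 3
  any_missing <- Reduce(`|`, lapply(visits[visit_fields()], is.na)) |
    (!is.na(visits$disposition) & visits$disposition == "missing")
  missing_fields <- !not_level3 & any_missing
  bad_dispo <- !not_level3 & !missing_fields &
    !(visits$disposition %in% c("admit", "discharge"))
  keep <- !(not_level3 | missing_fields | bad_dispo)
  tally <- structure(
    list(not_level3 = sum(not_level3),
         missing_fields = sum(missing_fields),
         non_standard_disposition = sum(bad_dispo),
         n_input = n,
         n_retained = sum(keep)),
    class = "exclusion_tally")
  list(visits = visits[keep, , drop = FALSE], tally = tally)
}

#' @export
print.exclusion_tally <- function(x, ...) {
  cat("Exclusion tally:", x$n_input, "visits in,", x$n_retained, "retained\n")
  cat("  not level-3:              ", x$not_level3, "\n")
  cat("  missing fields:           ", x$missing_fields, "\n")
  cat("  non-standard disposition: ", x$non_standard_disposition, "\n")
  invisible(x)
}

#' Random train/validation split
#'
#' Simple random partition of the visits, without stratification; the study
#' design checks post hoc that the two sets are statistically similar
#' ([similarity_report()]) rather than stratifying. The training set has
#' `round(fraction * n)` rows; the remainder goes to validation. The split
#' is deterministic given `seed`.
#'
#' @param visits Nonempty visit `data.frame`.
#' @param fraction Training fraction, strictly between 0 and 1 (study
#'   default 0.8).
#' @param seed Integer seed fixing the split.
#' @return A list of class `split_result` with `train`, `validation`,
#'   `seed`, `fraction`.
#' @export
split_train_validation <- function(visits, fraction = 0.8, seed = 1L) {
  stopifnot(is.data.frame(visits), nrow(visits) > 0L)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      is.na(fraction) || fraction <= 0 || fraction >= 1) {
    stop("'fraction' must be a single number strictly between 0 and 1")
  }
  n <- nrow(visits)
  n_train <- as.integer(round(fraction * n))
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  train_idx <- sort(sample.int(n, n_train))
  structure(
    list(train = visits[train_idx, , drop = FALSE],
         validation = visits[-train_idx, , drop = FALSE],
         seed = as.integer(seed),
         fraction = fraction),
    class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("Train/validation split: %d / %d rows (fraction %.3f, seed %d)\n",
              nrow(x$train), nrow(x$validation), x$fraction, x$seed))
  invisible(x)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Train-vs-validation similarity report
#'
#' For gender, age band, medical-history presence and chief-complaint
#' category, computes the within-disposition (admitted / discharged)
#' composition of the training and validation sets and compares each
#' category's proportion between the splits with a two-proportion test
#' (chi-squared without continuity correction). Mirrors the descriptive
#' table a triage-cohort study reports to confirm that a random split did
#' not imbalance the two sets.
#'
#' @param train,validation Nonempty post-filter visit `data.frame`s.
#' @return A `data.frame` with one row per variable level and disposition:
#'   counts, proportions in each split, their difference, and the p-value
#'   (`NA` when a level is absent from one split).
#' @export
similarity_report <- function(train, validation) {
  stopifnot(is.data.frame(train), nrow(train) > 0L,
            is.data.frame(validation), nrow(validation) > 0L)
  strata <- function(v) {
    switch(v,
           gender = function(d) ifelse(d$sex == 1, "male", "female"),
           age_band = function(d) as.character(age_band(d$age)),
           medical_history = function(d)
             ifelse(d$medical_history_score > 0, "with", "without"),
           cc_category = function(d) d$cc_category)
  }
  vars <- c("gender", "age_band", "medical_history", "cc_category")
  out <- list()
  for (v in vars) {
    f <- strata(v)
    for (dispo in c("admit", "discharge")) {
      tr <- f(train[train$disposition == dispo, , drop = FALSE])
      va <- f(validation[validation$disposition == dispo, , drop = FALSE])
      levels_v <- sort(unique(c(tr, va)))
      for (lev in levels_v) {
        n_tr <- sum(tr == lev); n_va <- sum(va == lev)
        p_tr <- if (length(tr)) n_tr / length(tr) else 0
        p_va <- if (length(va)) n_va / length(va) else 0
        pval <- NA_real_
        if (n_tr > 0L && n_va > 0L && length(tr) > 0L && length(va) > 0L) {
          pval <- suppressWarnings(
            prop.test(c(n_tr, n_va), c(length(tr), length(va)),
                      correct = FALSE)$p.value)
        }
        out[[length(out) + 1L]] <- data.frame(
          variable = v, level = lev, disposition = dispo,
          n_train = n_tr, n_validation = n_va,
          prop_train = p_tr, prop_validation = p_va,
          prop_diff = p_tr - p_va, p_value = pval,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
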
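#' Canonical model variables
#'
#' The ten triage-time variables, in the fixed order the model consumes:
#' age, sex, the six vital signs, the medical-history score and the
#' chief-complaint risk value. Ablation subsets are always expressed in
#' this order.
#'
#' @return Character vector of length 10.
#' @export
canonical_features <- function() {
  c("age", "sex", "temperature", "heart_rate", "respiratory_rate",
    "systolic_bp", "diastolic_bp", "mean_arterial_pressure",
    "medical_history_score", "cc_risk_value")
}

#' Preconfigured ablation subsets
#'
#' The four variable subsets of the ablation experiment: the full
#' ten-variable model; nine variables (all but the chief complaint); the
#' six-variable core (age, sex, heart rate, MAP, medical history, chief
#' complaint); and that core minus the chief complaint (five variables).
#'
#' @return Named list of character vectors.
#' @export
ablation_subsets <- function() {
  full <- canonical_features()
  six <- c("age", "sex", "heart_rate", "mean_arterial_pressure",
           "medical_history_score", "cc_risk_value")
  list(full_10 = full,
       no_cc_9 = setdiff(full, "cc_risk_value"),
       core_6 = six,
       core_no_cc_5 = setdiff(six, "cc_risk_value"))
}

#' Medical-history score
#'
#' Sums the configured integer points over a patient's disease
#' classifications and clamps the sum to the scale's 0-12 range; a patient
#' with no recorded medical history scores zero.
#'
#' @param classifications Character vector (possibly empty) of
#'   classification labels, all of which must appear in `scoring`.
#' @param scoring Named integer vector mapping classification label to
#'   points (see [default_history_scoring()]).
#' @return Integer score in `[0, 12]`.
#' @export
medical_history_score <- function(classifications,
                                  scoring = default_history_scoring()) {
  stopifnot(is.numeric(scoring), !is.null(names(scoring)))
  if (length(classifications) == 0L) return(0L)
  unknown <- setdiff(classifications, names(scoring))
  if (length(unknown) > 0L) {
    stop("unknown classification label(s): ",
         paste(unknown, collapse = ", "))
  }
  as.integer(min(12L, max(0L, sum(scoring[classifications]))))
}

#' Default medical-history scoring map
#'
#' The per-classification point values are site configuration, not part of
#' the published method; this default assigns one point to each of twelve
#' generic disease classifications so the score spans its full 0-12 range.
#'
#' @return Named integer vector of 12 classifications, 1 point each.
#' @export
default_history_scoring <- function() {
  labels <- c("cardiovascular", "cerebrovascular", "diabetes", "renal",
              "hepatic", "pulmonary", "malignancy", "immunologic",
              "psychiatric", "neurologic", "gastrointestinal",
              "musculoskeletal")
  structure(rep(1L, 12L), names = labels)
}

#' Encode visits as model feature vectors
#'
#' Builds the numeric feature matrix for a variable subset, in canonical
#' order. The chief-complaint risk value, when requested, is looked up in
#' the fitted [fit_cc_risk_table()] (unseen codes encode as 0). Values are
#' fed to the model unscaled; the first batch-normalization layer absorbs
#' scale.
#'
#' @param visits Post-filter visit `data.frame`.
#' @param table A `cc_risk_table` (required when `cc_risk_value` is in the
#'   subset).
#' @param subset Character vector of variable names, a nonempty subset of
#'   [canonical_features()].
#' @return Numeric matrix, one row per visit, columns named and ordered
#'   canonically.
#' @export
encode_features <- function(visits, table = NULL,
                            subset = canonical_features()) {
  stopifnot(is.data.frame(visits))
  if (length(subset) == 0L) stop("'subset' must be nonempty")
  bad <- setdiff(subset, canonical_features())
  if (length(bad) > 0L) {
    stop("unknown feature name(s): ", paste(bad, collapse = ", "))
  }
  subset <- canonical_features()[canonical_features() %in% subset]
  cols <- list()
  for (f in subset) {
    if (f == "cc_risk_value") {
      if (is.null(table)) {
        stop("a fitted cc_risk_table is required to encode cc_risk_value")
      }
      cols[[f]] <- lookup_risk(table, visits$cc_code)
    } else {
      cols[[f]] <- as.numeric(visits[[f]])
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- NULL
  m
}

#' Admission labels
#'
#' @param visits Post-filter visit `data.frame`.
#' @return Integer vector: admission coded 1, discharge 0.
#' @export
admission_labels <- function(visits) {
  as.integer(visits$disposition == "admit")
}
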
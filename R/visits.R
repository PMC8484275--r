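#' Visit-record schema
#'
#' One row per triage encounter. The sixteen columns and their types are the
#' package's exchange format: the cohort generator emits them, the CSV
#' reader/writer round-trips them, and every downstream stage consumes them.
#'
#' @return Character vector of the canonical column names, in order.
#' @export
visit_fields <- function() {
  c("visit_id", "patient_id", "triage_level", "age", "sex",
    "temperature", "heart_rate", "respiratory_rate",
    "systolic_bp", "diastolic_bp", "mean_arterial_pressure",
    "medical_history_score", "cc_code", "cc_category",
    "disposition", "hospital_outcome")
}

#' Chief-complaint categories
#'
#' The four top-level categories of the triage chief-complaint code system.
#'
#' @return Character vector of category labels.
#' @export
cc_categories <- function() {
  c("trauma", "nontraumatic_adult", "pediatrics", "env_emergency")
}

.dispositions <- c("admit", "discharge", "transfer", "against_advice",
                   "other", "missing")
.outcomes <- c("recovered", "deceased", "not_hospitalized")

.numeric_fields <- c("triage_level", "age", "sex", "temperature",
                     "heart_rate", "respiratory_rate", "systolic_bp",
                     "diastolic_bp", "mean_arterial_pressure",
                     "medical_history_score")
.character_fields <- c("visit_id", "patient_id", "cc_code", "cc_category",
                       "disposition", "hospital_outcome")

#' Read a visit CSV
#'
#' Reads a UTF-8 visit table with exactly the [visit_fields()] header.
#' Empty cells and the literal string `NA` are both treated as missing;
#' numeric columns are coerced and the categorical columns are checked
#' against their allowed levels (missing values are allowed before
#' filtering).
#'
#' @param path Path to a CSV file.
#' @return A `data.frame` of visits.
#' @seealso [write_visits()], [apply_inclusion_filters()]
#' @export
read_visits <- function(path) {
  df <- read.csv(path, colClasses = "character", na.strings = c("", "NA"),
                 fileEncoding = "UTF-8", check.names = FALSE)
  missing_cols <- setdiff(visit_fields(), names(df))
  if (length(missing_cols) > 0L) {
    stop("visit CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- df[visit_fields()]
  for (f in .numeric_fields) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- !is.na(df[[f]]) & is.na(v)
    if (any(bad)) {
      stop("non-numeric value in column '", f, "' at row ",
           which(bad)[1L])
    }
    df[[f]] <- v
  }
  .check_levels(df$cc_category, cc_categories(), "cc_category")
  .check_levels(df$disposition, .dispositions, "disposition")
  .check_levels(df$hospital_outcome, .outcomes, "hospital_outcome")
  df
}

.check_levels <- function(x, levels, name) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop("invalid ", name, " value '", x[which(bad)[1L]], "' at row ",
         which(bad)[1L])
  }
  invisible(TRUE)
}

#' Write a visit CSV
#'
#' Inverse of [read_visits()]: writes the canonical visit schema so that
#' reading the file back reproduces the input data frame.
#'
#' @param visits Visit `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path) {
  stopifnot(is.data.frame(visits))
  missing_cols <- setdiff(visit_fields(), names(visits))
  if (length(missing_cols) > 0L) {
    stop("visit data is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  out <- visits[visit_fields()]
  out$age <- ifelse(is.na(out$age), NA, sprintf("%.1f", out$age))
  out$temperature <- ifelse(is.na(out$temperature), NA,
                            sprintf("%.1f", out$temperature))
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Age bands used for cohort description
#'
#' Closed-open bands `[0,18)`, `[18,65)`, `[65,85)`, `[85,Inf)`, the strata
#' used in the similarity report and the synthetic cohort's age model.
#'
#' @param age Numeric vector of ages in years.
#' @return Factor with levels `0-17`, `18-64`, `65-84`, `>=85`.
#' @export
age_band <- function(age) {
  cut(age, breaks = c(0, 18, 65, 85, Inf), right = FALSE,
      labels = c("0-17", "18-64", "65-84", ">=85"))
}
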
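#' Risk value of a chief-complaint count triple
#'
#' The risk value of a chief-complaint code is the sum of its
#' hospitalization fraction and the death fraction among its hospitalized
#' patients:
#'
#' \deqn{v = \frac{n_{hr} + n_{hd}}{n_t} + \frac{n_{hd}}{n_{hr} + n_{hd}}}
#'
#' where `n_t` counts training visits with the code, `n_hr` those
#' hospitalized and recovered, `n_hd` those hospitalized and deceased.
#' The second term separates codes with equal admission counts but
#' different lethality. Both degenerate cases map to zero: `n_t = 0`
#' (code unseen in training) and `n_hr + n_hd = 0` (no hospitalizations,
#' so the death fraction has an empty denominator and the code carries no
#' admission risk). The value always lies in `[0, 2]`.
#'
#' @param n_t,n_hr,n_hd Non-negative integer vectors (recycled) with
#'   `n_hr + n_hd <= n_t`.
#' @return Numeric vector of risk values in `[0, 2]`.
#' @export
cc_risk_value <- function(n_t, n_hr, n_hd) {
  if (any(n_t < 0 | n_hr < 0 | n_hd < 0)) {
    stop("counts must be non-negative")
  }
  n_h <- n_hr + n_hd
  if (any(n_h > n_t)) {
    stop("hospitalized count exceeds total count (n_hr + n_hd > n_t)")
  }
  term1 <- ifelse(n_t > 0, n_h / n_t, 0)
  term2 <- ifelse(n_h > 0, n_hd / n_h, 0)
  term1 + term2
}

#' Fit the chief-complaint risk table
#'
#' Aggregates the training visits into per-code count triples
#' `(n_t, n_hr, n_hd)` and computes each code's risk value with
#' [cc_risk_value()]. The table covers exactly the codes present in the
#' training data; unseen codes look up as 0. Fitting is a pure counting
#' operation on the training set only — validation records must never be
#' passed here in the standard pipeline (see [refit_with_validation()] for
#' the deliberate leakage diagnostic).
#'
#' @param train Post-filter training visits with `hospital_outcome` set.
#' @return A `cc_risk_table`: data frame of `code, n_t, n_hr, n_hd, v`
#'   plus attributes `fitted_on_n` and `default_for_unseen` (0).
#' @export
fit_cc_risk_table <- function(train) {
  stopifnot(is.data.frame(train))
  bad_admit <- train$disposition == "admit" &
    train$hospital_outcome == "not_hospitalized"
  bad_disch <- train$disposition == "discharge" &
    train$hospital_outcome != "not_hospitalized"
  if (any(bad_admit | bad_disch)) {
    stop("data integrity: disposition and hospital_outcome disagree at row ",
         which(bad_admit | bad_disch)[1L])
  }
  codes <- sort(unique(train$cc_code))
  n_t <- as.integer(table(factor(train$cc_code, levels = codes)))
  adm <- train$disposition == "admit"
  n_hr <- as.integer(table(factor(
    train$cc_code[adm & train$hospital_outcome == "recovered"],
    levels = codes)))
  n_hd <- as.integer(table(factor(
    train$cc_code[adm & train$hospital_outcome == "deceased"],
    levels = codes)))
  entries <- data.frame(code = codes, n_t = n_t, n_hr = n_hr, n_hd = n_hd,
                        v = cc_risk_value(n_t, n_hr, n_hd),
                        stringsAsFactors = FALSE)
  structure(entries, class = c("cc_risk_table", "data.frame"),
            fitted_on_n = nrow(train), default_for_unseen = 0)
}

#' Look up chief-complaint risk values
#'
#' @param table A fitted `cc_risk_table`.
#' @param code Character vector of chief-complaint codes.
#' @return Numeric vector of risk values; codes absent from the table
#'   return 0.
#' @export
lookup_risk <- function(table, code) {
  stopifnot(inherits(table, "cc_risk_table"))
  v <- table$v[match(code, table$code)]
  v[is.na(v)] <- attr(table, "default_for_unseen")
  v
}

#' @export
print.cc_risk_table <- function(x, ...) {
  cat(sprintf("Chief-complaint risk table: %d codes fitted on %d visits\n",
              nrow(x), attr(x, "fitted_on_n")))
  print.data.frame(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Serialize a risk table
#'
#' Writes the per-code counts and risk values as CSV (`code, n_t, n_hr,
#' n_hd, v`) or JSON (entries plus the fit metadata).
#'
#' @param table A `cc_risk_table`.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_cc_risk_table <- function(table, path) {
  stopifnot(inherits(table, "cc_risk_table"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(fitted_on_n = attr(table, "fitted_on_n"),
           default_for_unseen = attr(table, "default_for_unseen"),
           entries = as.data.frame(table)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Refit the risk table with validation data folded in (leakage diagnostic)
#'
#' Deliberately refits the chief-complaint risk table on the union of the
#' training and validation sets and reports the per-code change in risk
#' value. This quantifies how much the encoder would shift if validation
#' outcomes leaked into the fit; it exists only as a named diagnostic and
#' is never part of the prediction pipeline.
#'
#' @param train,validation Post-filter visit data frames.
#' @return Data frame of `code, v_train, v_pooled, delta`.
#' @export
refit_with_validation <- function(train, validation) {
  t1 <- fit_cc_risk_table(train)
  t2 <- fit_cc_risk_table(rbind(train, validation))
  codes <- sort(unique(c(t1$code, t2$code)))
  data.frame(code = codes,
             v_train = lookup_risk(t1, codes),
             v_pooled = lookup_risk(t2, codes),
             delta = lookup_risk(t2, codes) - lookup_risk(t1, codes),
             stringsAsFactors = FALSE)
}
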
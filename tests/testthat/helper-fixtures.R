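# Minimal complete visit record(s) for hand-built fixtures; fields can be
# overridden per record.
toy_visit <- function(n = 1L, ...) {
  n1 <- max(n, 1L)
  base <- data.frame(
    visit_id = sprintf("v%03d", seq_len(n1)),
    patient_id = sprintf("p%03d", seq_len(n1)),
    triage_level = 3L,
    age = 40.0,
    sex = 1L,
    temperature = 37.0,
    heart_rate = 90L,
    respiratory_rate = 18L,
    systolic_bp = 130L,
    diastolic_bp = 80L,
    mean_arterial_pressure = 97L,
    medical_history_score = 0L,
    cc_code = "NTA01",
    cc_category = "nontraumatic_adult",
    disposition = "discharge",
    hospital_outcome = "not_hospitalized",
    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base[seq_len(n), , drop = FALSE]
}

# Build a visit set realizing given per-code count triples (n_t, n_hr, n_hd),
# used as the independent route to the risk-value arithmetic.
visits_from_triples <- function(triples) {
  rows <- list()
  for (i in seq_len(nrow(triples))) {
    code <- triples$code[i]
    n_t <- triples$n_t[i]; n_hr <- triples$n_hr[i]; n_hd <- triples$n_hd[i]
    n_disch <- n_t - n_hr - n_hd
    status <- c(rep("hr", n_hr), rep("hd", n_hd), rep("d", n_disch))
    if (length(status) == 0L) next
    v <- toy_visit(length(status), cc_code = code)
    v$disposition <- ifelse(status == "d", "discharge", "admit")
    v$hospital_outcome <- c(hr = "recovered", hd = "deceased",
                            d = "not_hospitalized")[status]
    rows[[length(rows) + 1L]] <- v
  }
  out <- do.call(rbind, rows)
  out$visit_id <- sprintf("v%06d", seq_len(nrow(out)))
  out
}

small_cohort <- function(n = 5000L, seed = 11L) {
  generate_cohort(default_cohort_config(n_visits = n, seed = seed))
}
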
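#' Generate a synthetic visit cohort
#'
#' Draws `config$n_visits` complete level-3 visit records from the
#' class-conditional model described in [default_cohort_config()]:
#' disposition first, then sex, age (band mixture with per-band shapes),
#' chief-complaint category and code, correlated vital signs, derived
#' mean arterial pressure, and the medical-history score. Admitted
#' patients receive a recovered/deceased in-hospital outcome drawn from
#' their code's mortality; discharged patients are `not_hospitalized`.
#' Generation is fully deterministic given `config$seed`.
#'
#' @param config A validated `cohort_config`.
#' @return Visit `data.frame` with the [visit_fields()] schema; every
#'   record satisfies `dbp <= MAP <= sbp`.
#' @export
generate_cohort <- function(config = default_cohort_config()) {
  validate_cohort_config(config)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  .generate_core(config)
}

.sample_by_class <- function(y, prob_matrix) {
  # one categorical draw per row; row y+1 of prob_matrix gives the pmf
  n <- length(y)
  p <- prob_matrix[y + 1L, , drop = FALSE]
  cum <- t(apply(p, 1L, cumsum))
  u <- runif(n)
  max.col(cum >= u, ties.method = "first")
}

.generate_core <- function(config) {
  n <- config$n_visits
  y <- rbinom(n, 1L, config$admission_rate)
  cls <- y + 1L  # 1 = discharge, 2 = admit

  sex <- rbinom(n, 1L, config$sex_male_prob[cls])

  band <- .sample_by_class(y, config$age_band_probs)
  age <- numeric(n)
  i1 <- band == 1L; i2 <- band == 2L; i3 <- band == 3L; i4 <- band == 4L
  age[i1] <- runif(sum(i1), 0, 18)
  ab <- config$age_band2_beta
  age[i2] <- 18 + 47 * rbeta(sum(i2), ab[cls[i2], 1], ab[cls[i2], 2])
  age[i3] <- runif(sum(i3), 65, 85)
  age[i4] <- 85 + pmin(rexp(sum(i4), 1 / config$age_band4_mean),
                       config$age_band4_cap)
  age <- round(pmin(age, 110), 1)
  age[i1] <- pmin(age[i1], 17.9)  # band-1 rounding must not cross 18

  child <- age < 18
  category <- character(n)
  u <- runif(n)
  is_peds <- child & u < config$child_peds_prob[cls]
  category[is_peds] <- "pediatrics"
  rest <- child & !is_peds
  category[rest] <- ifelse(runif(sum(rest)) < config$child_rest_split["trauma"],
                           "trauma", "env_emergency")
  adult <- !child
  adult_idx <- .sample_by_class(y[adult], config$adult_category_probs)
  category[adult] <- colnames(config$adult_category_probs)[adult_idx]

  # chief-complaint codes: per (category, disposition) cell, weights are
  # prevalence (discharged) or prevalence x enrichment (admitted)
  cc_code <- character(n)
  catalogue <- config$cc_catalogue
  for (g in cc_categories()) {
    sub <- catalogue[catalogue$category == g, , drop = FALSE]
    for (yy in 0:1) {
      rows <- which(category == g & y == yy)
      if (length(rows) == 0L) next
      w <- if (yy == 1L) sub$weight * sub$enrichment else sub$weight
      cc_code[rows] <- if (nrow(sub) == 1L) sub$code else
        sample(sub$code, length(rows), replace = TRUE, prob = w)
    }
  }

  mu <- config$vital_means
  sds <- config$vital_sds
  L <- chol(config$vital_corr)
  z <- matrix(rnorm(n * 5L), n, 5L) %*% L
  vit <- mu[cls, , drop = FALSE] + sweep(z, 2L, sds, `*`)
  vit[, 1] <- round(vit[, 1], 1)
  vit[, 2:5] <- round(vit[, 2:5])
  for (j in 1:5) {
    vit[, j] <- pmin(pmax(vit[, j], config$vital_bounds["lower", j]),
                     config$vital_bounds["upper", j])
  }
  swap <- vit[, 5] >= vit[, 4]
  vit[swap, 5] <- vit[swap, 4] - 1

  noise <- sample(config$map_noise$values, n, replace = TRUE,
                  prob = config$map_noise$probs)
  map <- round((vit[, 4] + 2 * vit[, 5]) / 3) + noise
  map <- pmin(pmax(map, vit[, 5]), vit[, 4])

  has_hist <- rbinom(n, 1L, config$history_has_prob[cls])
  score <- integer(n)
  hh <- has_hist == 1L
  score[hh] <- 1L + pmin(rpois(sum(hh), config$history_lambda[cls[hh]]), 11L)

  mort <- catalogue$mortality[match(cc_code, catalogue$code)]
  deceased <- y == 1L & runif(n) < mort
  outcome <- ifelse(y == 1L, ifelse(deceased, "deceased", "recovered"),
                    "not_hospitalized")

  pool <- max(1L, as.integer(round(n / config$visits_per_patient)))
  patient_id <- sprintf("p%07d", sample.int(pool, n, replace = TRUE))

  data.frame(
    visit_id = sprintf("v%08d", seq_len(n)),
    patient_id = patient_id,
    triage_level = 3L,
    age = age,
    sex = sex,
    temperature = vit[, 1],
    heart_rate = as.integer(vit[, 2]),
    respiratory_rate = as.integer(vit[, 3]),
    systolic_bp = as.integer(vit[, 4]),
    diastolic_bp = as.integer(vit[, 5]),
    mean_arterial_pressure = as.integer(map),
    medical_history_score = score,
    cc_code = cc_code,
    cc_category = category,
    disposition = ifelse(y == 1L, "admit", "discharge"),
    hospital_outcome = outcome,
    stringsAsFactors = FALSE)
}

#' Generate a raw (pre-filter) visit stream
#'
#' Like [generate_cohort()], but additionally corrupts records the way a
#' real extraction would: with probability `rate_other_level` the triage
#' level is replaced by a non-3 level, with probability
#' `rate_missing_fields` one randomly chosen triage field is blanked, and
#' with probability `rate_non_standard_disposition` the disposition is
#' replaced by transfer / against-advice / other. The three corruptions
#' are drawn independently per record, so the expected retained fraction
#' under [apply_inclusion_filters()] is the product of the three survival
#' probabilities. With all three rates zero the output passes the filters
#' unchanged.
#'
#' @param config A validated `cohort_config`.
#' @return Visit `data.frame`, possibly with missing fields and
#'   non-standard levels/dispositions.
#' @export
generate_raw_stream <- function(config = default_cohort_config()) {
  validate_cohort_config(config)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  visits <- .generate_core(config)
  n <- nrow(visits)

  relevel <- runif(n) < config$rate_other_level
  if (any(relevel)) {
    visits$triage_level[relevel] <- sample(
      c(1L, 2L, 4L, 5L), sum(relevel), replace = TRUE,
      prob = c(0.10, 0.45, 0.30, 0.15))
  }

  maskable <- c("age", "sex", "temperature", "heart_rate",
                "respiratory_rate", "systolic_bp", "diastolic_bp",
                "mean_arterial_pressure", "medical_history_score",
                "cc_code")
  mask <- which(runif(n) < config$rate_missing_fields)
  if (length(mask) > 0L) {
    fields <- sample(maskable, length(mask), replace = TRUE)
    for (f in maskable) {
      visits[mask[fields == f], f] <- NA
    }
  }

  redisp <- runif(n) < config$rate_non_standard_disposition
  if (any(redisp)) {
    visits$disposition[redisp] <- sample(
      c("transfer", "against_advice", "other"), sum(redisp),
      replace = TRUE, prob = c(0.5, 0.3, 0.2))
    visits$hospital_outcome[redisp] <- "not_hospitalized"
  }
  visits
}

#' Bayes-optimal admission score of a generated cohort
#'
#' Because the generator is class-conditional with every per-disposition
#' density known in closed form, the exact posterior log-odds of
#' admission given a record's observable fields is available:
#'
#' \deqn{\eta(x) = \mathrm{logit}(\pi) + \sum_k \log
#'   \frac{p_k(x_k \mid \mathrm{admit})}{p_k(x_k \mid \mathrm{discharge})}}
#'
#' summing the sex, age (band and within-band density), category-given-age,
#' code-given-category, correlated-vitals (a linear discriminant term,
#' shared covariance) and medical-history contributions. MAP is derived
#' from the pressures plus disposition-independent noise, so it carries no
#' additional information and is omitted. This score is the Bayes-optimal
#' ranking up to recording granularity (rounding and rare boundary
#' clamping), so its AUC on a generated cohort upper-bounds — within CI
#' overlap — what any model trained on the observables can achieve.
#'
#' @param visits Generated (post-filter) visit `data.frame`.
#' @param config The `cohort_config` that generated them.
#' @return Numeric vector of posterior log-odds, one per visit.
#' @export
true_admission_logit <- function(visits, config = default_cohort_config()) {
  n <- nrow(visits)
  eta <- rep(log(config$admission_rate / (1 - config$admission_rate)), n)

  p <- config$sex_male_prob
  eta <- eta + ifelse(visits$sex == 1, log(p["admit"] / p["discharge"]),
                      log((1 - p["admit"]) / (1 - p["discharge"])))

  band <- as.integer(age_band(visits$age))
  bp <- config$age_band_probs
  eta <- eta + log(bp["admit", band] / bp["discharge", band])
  i2 <- band == 2L
  if (any(i2)) {
    u <- (visits$age[i2] - 18) / 47
    u <- pmin(pmax(u, 1e-6), 1 - 1e-6)
    ab <- config$age_band2_beta
    eta[i2] <- eta[i2] + dbeta(u, ab["admit", 1], ab["admit", 2], log = TRUE) -
      dbeta(u, ab["discharge", 1], ab["discharge", 2], log = TRUE)
  }

  child <- visits$age < 18
  pp <- config$child_peds_prob
  split <- config$child_rest_split
  cat_child_p <- function(cls) {
    c(trauma = unname((1 - pp[cls]) * split["trauma"]),
      nontraumatic_adult = 0,
      pediatrics = unname(pp[cls]),
      env_emergency = unname((1 - pp[cls]) * split["env_emergency"]))
  }
  adult_p <- config$adult_category_probs
  cat_lr <- numeric(n)
  for (g in cc_categories()) {
    idx <- visits$cc_category == g
    lr_child <- log(cat_child_p("admit")[g] / cat_child_p("discharge")[g])
    pa <- if (g %in% colnames(adult_p)) adult_p["admit", g] else 0
    pd <- if (g %in% colnames(adult_p)) adult_p["discharge", g] else 0
    lr_adult <- log(pa / pd)
    cat_lr[idx & child] <- lr_child
    cat_lr[idx & !child] <- lr_adult
  }
  eta <- eta + cat_lr

  catalogue <- config$cc_catalogue
  code_lr <- numeric(nrow(catalogue))
  for (g in cc_categories()) {
    rows <- catalogue$category == g
    w <- catalogue$weight[rows]
    e <- catalogue$enrichment[rows]
    code_lr[rows] <- log(e) + log(sum(w)) - log(sum(w * e))
  }
  m <- match(visits$cc_code, catalogue$code)
  eta <- eta + ifelse(is.na(m), 0, code_lr[m])

  mu <- config$vital_means
  sds <- config$vital_sds
  sigma <- diag(sds) %*% config$vital_corr %*% diag(sds)
  w <- solve(sigma, mu["admit", ] - mu["discharge", ])
  x <- as.matrix(visits[, config$vital_names])
  centered <- sweep(x, 2L, (mu["admit", ] + mu["discharge", ]) / 2, `-`)
  eta <- eta + drop(centered %*% w)

  q <- config$history_has_prob
  lam <- config$history_lambda
  s <- visits$medical_history_score
  hist_lr <- ifelse(
    s == 0,
    log((1 - q["admit"]) / (1 - q["discharge"])),
    log(q["admit"] / q["discharge"]) +
      ifelse(s >= 12,
             ppois(10, lam["admit"], lower.tail = FALSE, log.p = TRUE) -
               ppois(10, lam["discharge"], lower.tail = FALSE, log.p = TRUE),
             dpois(pmax(s - 1, 0), lam["admit"], log = TRUE) -
               dpois(pmax(s - 1, 0), lam["discharge"], log = TRUE)))
  eta + hist_lr
}
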
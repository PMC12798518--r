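# Shared fixtures and independent oracles used across test files.

# Minimal cohort row constructor for linkage / ascertainment tests.
person_row <- function(id, cohort = "A", dob = "1985-01-01",
                       enroll = "2015-06-01", score = 5,
                       selfreport = NA_real_, true_status = 0L) {
  tibble::tibble(person_id = id, cohort_label = cohort,
                 date_of_birth = as.Date(dob),
                 enrollment_date = as.Date(enroll),
                 completeness_score = score,
                 selfreport_flag = selfreport,
                 true_status = true_status)
}

enc_row <- function(id, date, setting = "outpatient", dx = "mood") {
  tibble::tibble(person_id = id, encounter_date = as.Date(date),
                 setting = setting, dx_group = dx)
}

# Brute-force oracle for the administrative case rule: enumerate every
# encounter and every pair of encounters, independently of the package's
# implementation.
admin_oracle <- function(encounters, person, entry_date, lookback_years = 5) {
  entry_date <- as.Date(entry_date)
  lb_start <- entry_date - round(lookback_years * 365.25)
  e <- encounters[encounters$person_id == person &
                    encounters$dx_group %in% c("mood", "anxiety") &
                    encounters$encounter_date >= lb_start &
                    encounters$encounter_date <= entry_date, , drop = FALSE]
  if (nrow(e) == 0L) return(0L)
  if (any(e$setting == "inpatient")) return(1L)
  od <- e$encounter_date[e$setting == "outpatient"]
  if (length(od) >= 2L) {
    for (i in seq_along(od)) {
      for (j in seq_along(od)) {
        if (i < j && od[i] != od[j] &&
            abs(as.numeric(od[i] - od[j])) <= 730) {
          return(1L)
        }
      }
    }
  }
  0L
}

# Random encounter set for one person, spanning in/out of the lookback.
random_encounters <- function(id, entry_date, n) {
  tibble::tibble(
    person_id = id,
    encounter_date = as.Date(entry_date) +
      sample(-2500:100, n, replace = TRUE),
    setting = sample(c("inpatient", "outpatient"), n, replace = TRUE,
                     prob = c(0.15, 0.85)),
    dx_group = sample(c("mood", "anxiety", "other"), n, replace = TRUE))
}

# Log marginal likelihood by quadrature of the scaled integrand, an
# independent check on the closed form.
log_evidence_quadrature <- function(alpha, beta, n, k) {
  logf <- function(p) {
    dbeta(p, alpha, beta, log = TRUE) + k * log(p) + (n - k) * log1p(-p)
  }
  mode <- (alpha + k - 1) / (alpha + beta + n - 2)
  c0 <- logf(mode)
  val <- stats::integrate(function(p) exp(logf(p) - c0), 0, 1,
                          rel.tol = 1e-12)$value
  c0 + log(val)
}
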
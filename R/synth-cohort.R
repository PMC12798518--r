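# Synthetic linked two-cohort generator with known ground truth.
#
# The generator draws a person-level true disease status, then overlays two
# imperfect measurement processes (a self-report diagnostic instrument and
# administrative claims coding, each with its own sensitivity/specificity),
# duplicate enrollment across the cohorts, incomplete instrument
# administration, and encounter streams constructed to be exactly
# consistent with the intended administrative flag — so the claims
# algorithm can be validated by round-trip.

#' Configuration for the synthetic linked-cohort generator
#'
#' Defaults emulate a two-cohort opioid-agonist-treatment study: cohort A
#' of 1,061 persons (after duplicate exclusion; 272 of 1,333 dual-enrolled)
#' of whom about 52% complete the diagnostic instrument, a second cohort of
#' 2,369 persons, true prevalence 0.59, self-report sensitivity/specificity
#' 0.95/0.84 (meta-analytic values for major depression) and administrative
#' coding sensitivity/specificity 0.629/0.938 (validation values for
#' claims-derived depression diagnoses).
#'
#' @param true_prevalence True probability of the condition, in (0, 1).
#' @param n_cohort_a,n_cohort_b Cohort sizes (positive integers).
#' @param duplicate_rate Fraction of cohort A also enrolled in cohort B;
#'   `round(duplicate_rate * n_cohort_a)` persons appear in both cohorts.
#' @param instrument_completion_rate Probability a cohort-A person
#'   completes the self-report instrument.
#' @param selfreport_sens,selfreport_spec Sensitivity and specificity of
#'   the self-report instrument.
#' @param admin_sens,admin_spec Sensitivity and specificity of the
#'   administrative coding process.
#' @param lookback_years Pre-entry lookback for the claims algorithm; must
#'   cover at least the 24-month pairing window.
#' @param enrollment_window_a,enrollment_window_b Date ranges (length-2,
#'   coercible to Date) for enrollment in each cohort.
#' @param censor_rate Probability a person is flagged censored.
#' @param demo_margins Named list of demographic targets: per-group age
#'   mean/sd and proportions female, single and unemployed (cases and
#'   non-cases separately).
#' @param seed Integer seed; identical configurations produce bit-identical
#'   tables.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(true_prevalence = 0.59,
                       n_cohort_a = 1061,
                       n_cohort_b = 2369,
                       duplicate_rate = 272 / 1061,
                       instrument_completion_rate = 549 / 1061,
                       selfreport_sens = 0.95,
                       selfreport_spec = 0.84,
                       admin_sens = 0.629,
                       admin_spec = 0.938,
                       lookback_years = 5,
                       enrollment_window_a = c("2011-06-01", "2017-04-30"),
                       enrollment_window_b = c("2018-05-01", "2021-04-30"),
                       censor_rate = 0,
                       demo_margins = list(
                         age_mean_case = 37.4, age_sd_case = 10.9,
                         age_mean_noncase = 40.1, age_sd_noncase = 11.4,
                         female_case = 0.559, female_noncase = 0.319,
                         single_case = 0.707, single_noncase = 0.660,
                         unemployed_case = 0.698, unemployed_noncase = 0.550),
                       seed = 123) {
  check_prob(true_prevalence, "true_prevalence")
  n_cohort_a <- check_count(n_cohort_a, "n_cohort_a")
  n_cohort_b <- check_count(n_cohort_b, "n_cohort_b")
  for (p in c("duplicate_rate", "instrument_completion_rate",
              "selfreport_sens", "selfreport_spec", "admin_sens",
              "admin_spec", "censor_rate")) {
    check_prob(get(p), p)
  }
  if (!is.numeric(lookback_years) || lookback_years <= 0 ||
      lookback_years * 12 < 24) {
    abort("`lookback_years` must be positive and cover at least 24 months.",
          class = "prevbayes_config_error")
  }
  n_dup <- as.integer(round(duplicate_rate * n_cohort_a))
  if (n_dup > min(n_cohort_a, n_cohort_b)) {
    abort("duplicate_rate implies more duplicates than either cohort holds.",
          class = "prevbayes_config_error")
  }
  wa <- as.Date(enrollment_window_a)
  wb <- as.Date(enrollment_window_b)
  if (any(is.na(wa)) || any(is.na(wb)) || wa[1] > wa[2] || wb[1] > wb[2]) {
    abort("Enrollment windows must be valid ascending date ranges.",
          class = "prevbayes_config_error")
  }
  structure(list(true_prevalence = true_prevalence,
                 n_cohort_a = n_cohort_a, n_cohort_b = n_cohort_b,
                 duplicate_rate = duplicate_rate, n_duplicates = n_dup,
                 instrument_completion_rate = instrument_completion_rate,
                 selfreport_sens = selfreport_sens,
                 selfreport_spec = selfreport_spec,
                 admin_sens = admin_sens, admin_spec = admin_spec,
                 lookback_years = lookback_years,
                 enrollment_window_a = wa, enrollment_window_b = wb,
                 censor_rate = censor_rate, demo_margins = demo_margins,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> prevalence %.3f | cohorts %d + %d (%d duplicates)\n",
                     "  instrument completion %.3f, sens/spec %.3f/%.3f\n",
                     "  admin sens/spec %.3f/%.3f, lookback %g y, seed %d\n"),
              x$true_prevalence, x$n_cohort_a, x$n_cohort_b, x$n_duplicates,
              x$instrument_completion_rate, x$selfreport_sens, x$selfreport_spec,
              x$admin_sens, x$admin_spec, x$lookback_years, x$seed))
  invisible(x)
}

runif_date <- function(n, window) {
  window[1] + floor(runif(n) * (as.numeric(window[2] - window[1]) + 1))
}

draw_demographics <- function(true_status, margins) {
  n <- length(true_status)
  case <- true_status == 1L
  age <- numeric(n)
  age[case] <- rnorm(sum(case), margins$age_mean_case, margins$age_sd_case)
  age[!case] <- rnorm(sum(!case), margins$age_mean_noncase, margins$age_sd_noncase)
  age <- pmax(age, 16)
  p_female <- ifelse(case, margins$female_case, margins$female_noncase)
  p_single <- ifelse(case, margins$single_case, margins$single_noncase)
  p_unemp <- ifelse(case, margins$unemployed_case, margins$unemployed_noncase)
  tibble(age_years = round(age, 1),
         sex = ifelse(runif(n) < p_female, "female", "male"),
         marital_status = ifelse(runif(n) < p_single, "single", "in_relationship"),
         employment_status = ifelse(runif(n) < p_unemp, "unemployed", "employed"))
}

#' Generate the synthetic two-cohort population
#'
#' Draws a person-level true status `Bernoulli(true_prevalence)`,
#' demographics matching the configured margins in expectation, enrollment
#' dates uniform over each cohort's window, and injects exactly
#' `round(duplicate_rate * n_cohort_a)` persons into both cohorts (same
#' person and date of birth, different enrollment date and completeness
#' score). Instrument completion is assigned completely at random to
#' cohort-A rows; the second cohort is never administered the instrument.
#'
#' @param config A [sim_config].
#' @return A tibble with one row per cohort record (a duplicated person
#'   contributes one row per cohort): `person_id`, `cohort_label`,
#'   `date_of_birth`, `enrollment_date`, `age_years`, `sex`,
#'   `marital_status`, `employment_status`, `completeness_score`,
#'   `instrument_completed`, `selfreport_flag` (NA until
#'   [simulate_self_report()]), `censored`, and the held-out `true_status`.
#' @examples
#' pop <- generate_population(sim_config(n_cohort_a = 50, n_cohort_b = 30))
#' dplyr::count(pop, cohort_label)
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(chain_seed(config$seed, 1L))
  n_a <- config$n_cohort_a
  n_b <- config$n_cohort_b
  n_dup <- config$n_duplicates
  n_persons <- n_a + n_b - n_dup

  person_id <- sprintf("P%06d", seq_len(n_persons))
  true_status <- as.integer(runif(n_persons) < config$true_prevalence)
  demo <- draw_demographics(true_status, config$demo_margins)

  # persons 1..n_a form cohort A; the first n_dup of them re-enroll in B;
  # persons (n_a+1)..n_persons are B-only
  idx_a <- seq_len(n_a)
  idx_b <- c(seq_len(n_dup), seq.int(n_a + 1L, length.out = n_b - n_dup))

  enroll_a <- runif_date(n_a, config$enrollment_window_a)
  enroll_b <- runif_date(n_b, config$enrollment_window_b)
  # date of birth fixed per person from the age drawn at first enrollment
  first_enroll <- c(enroll_a,
                    enroll_b[seq.int(n_dup + 1L, length.out = n_b - n_dup)])
  dob <- first_enroll - as.integer(round(demo$age_years * 365.25))

  score_a <- sample(4:8, n_a, replace = TRUE)
  # duplicate B records must differ in completeness from their A record
  score_b_dup <- vapply(seq_len(n_dup), function(i) {
    sample(setdiff(4:8, score_a[i]), 1L)
  }, integer(1))
  score_b_new <- sample(4:8, n_b - n_dup, replace = TRUE)

  rows_a <- tibble(
    person_id = person_id[idx_a],
    cohort_label = "A",
    date_of_birth = dob[idx_a],
    enrollment_date = enroll_a,
    completeness_score = score_a,
    true_status = true_status[idx_a]) |>
    dplyr::bind_cols(demo[idx_a, ])
  rows_b <- tibble(
    person_id = person_id[idx_b],
    cohort_label = "B",
    date_of_birth = dob[idx_b],
    enrollment_date = enroll_b,
    completeness_score = c(score_b_dup, score_b_new),
    true_status = true_status[idx_b]) |>
    dplyr::bind_cols(demo[idx_b, ])

  pop <- dplyr::bind_rows(rows_a, rows_b)
  pop$instrument_completed <- pop$cohort_label == "A" &
    runif(nrow(pop)) < config$instrument_completion_rate
  pop$selfreport_flag <- NA_real_
  pop$censored <- as.integer(runif(nrow(pop)) < config$censor_rate)
  dplyr::select(pop, "person_id", "cohort_label", "date_of_birth",
                "enrollment_date", "age_years", "sex", "marital_status",
                "employment_status", "completeness_score",
                "instrument_completed", "selfreport_flag", "censored",
                "true_status")
}

#' Overlay the imperfect self-report instrument on a cohort
#'
#' For each person who completed the instrument, the self-report flag is
#' drawn as 1 with probability `selfreport_sens` when the true status is 1
#' and with probability `1 - selfreport_spec` when it is 0; non-completers
#' keep a missing flag. The apparent (observed) prevalence therefore
#' converges to `sens * pi + (1 - spec) * (1 - pi)`.
#'
#' @param cohort A tibble from [generate_population()] (needs
#'   `true_status` and `instrument_completed`).
#' @param config The [sim_config] used to generate it.
#' @return The cohort with `selfreport_flag` filled in (0/1/NA).
#' @export
simulate_self_report <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- as_tibble(cohort)
  if (!all(c("true_status", "instrument_completed") %in% names(cohort))) {
    abort("`cohort` must carry `true_status` and `instrument_completed`.",
          class = "prevbayes_schema_error")
  }
  set.seed(chain_seed(config$seed, 2L))
  p_pos <- ifelse(cohort$true_status == 1L,
                  config$selfreport_sens, 1 - config$selfreport_spec)
  flag <- as.numeric(runif(nrow(cohort)) < p_pos)
  cohort$selfreport_flag <- ifelse(cohort$instrument_completed, flag, NA_real_)
  cohort
}

#' Generate administrative encounter streams consistent with intended flags
#'
#' First draws each person's *intended* administrative flag from the true
#' status via `admin_sens` / `admin_spec`, then materialises an encounter
#' stream that the claims case definition will classify exactly as
#' intended: flagged persons receive either one inpatient mood/anxiety
#' code or two outpatient codes on distinct dates within 24 months (all
#' inside the lookback window before their entry date); unflagged persons
#' receive only non-qualifying patterns (nothing, a single outpatient
#' code, two outpatient codes more than 24 months apart, or codes in an
#' unrelated diagnosis group). Every generated encounter is dated on or
#' before the person's enrollment date.
#'
#' For duplicated persons the entry date is taken from the record that
#' deterministic linkage retains (most complete, then earliest enrollment,
#' then cohort A), so the round trip through [admin_case_flags()] on the
#' linked table is exact.
#'
#' @inheritParams simulate_self_report
#' @return An encounter tibble `{person_id, encounter_date, setting,
#'   dx_group}`, with the intended flags attached as attribute
#'   `intended_admin_flag` (tibble `{person_id, admin_case_true,
#'   entry_date}`).
#' @export
generate_encounters <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  cohort <- as_tibble(cohort)
  if (!"true_status" %in% names(cohort)) {
    abort("`cohort` must carry `true_status`.", class = "prevbayes_schema_error")
  }
  set.seed(chain_seed(config$seed, 3L))
  lb <- days_per_lookback(config$lookback_years)

  persons <- cohort |>
    dplyr::arrange(.data$person_id, dplyr::desc(.data$completeness_score),
                   .data$enrollment_date, .data$cohort_label) |>
    dplyr::distinct(.data$person_id, .keep_all = TRUE)
  n <- nrow(persons)
  entry <- as.Date(persons$enrollment_date)

  p_flag <- ifelse(persons$true_status == 1L, config$admin_sens,
                   1 - config$admin_spec)
  flag <- as.integer(runif(n) < p_flag)

  dx_pool <- function(k) sample(c("mood", "anxiety"), k, replace = TRUE,
                                prob = c(0.6, 0.4))
  # qualifying patterns for flagged persons
  pat_pos <- ifelse(runif(n) < 0.3, "inpatient", "pair")
  # decoy patterns for unflagged persons
  pat_neg <- sample(c("none", "single", "distant", "other_only"), n,
                    replace = TRUE, prob = c(0.3, 0.3, 0.2, 0.2))
  if (lb < 732L) pat_neg[pat_neg == "distant"] <- "single"
  pattern <- ifelse(flag == 1L, pat_pos, pat_neg)

  pieces <- list()
  i_in <- which(pattern == "inpatient")
  if (length(i_in)) {
    pieces$inpat <- tibble(
      person_id = persons$person_id[i_in],
      encounter_date = entry[i_in] - floor(runif(length(i_in)) * (lb + 1)),
      setting = "inpatient",
      dx_group = dx_pool(length(i_in)))
  }
  i_pr <- which(pattern == "pair")
  if (length(i_pr)) {
    o1 <- 1L + floor(runif(length(i_pr)) * lb)         # 1..lb days before entry
    gap <- 1L + floor(runif(length(i_pr)) * pmin(WINDOW_DAYS, o1))
    pieces$pair <- tibble(
      person_id = rep(persons$person_id[i_pr], 2L),
      encounter_date = c(entry[i_pr] - o1, entry[i_pr] - o1 + gap),
      setting = "outpatient",
      dx_group = rep(dx_pool(length(i_pr)), 2L))
  }
  i_sg <- which(pattern == "single")
  if (length(i_sg)) {
    pieces$single <- tibble(
      person_id = persons$person_id[i_sg],
      encounter_date = entry[i_sg] - floor(runif(length(i_sg)) * (lb + 1)),
      setting = "outpatient",
      dx_group = dx_pool(length(i_sg)))
  }
  i_ds <- which(pattern == "distant")
  if (length(i_ds)) {
    o1 <- (WINDOW_DAYS + 1L) +
      floor(runif(length(i_ds)) * (lb - WINDOW_DAYS))   # 731..lb
    gap <- (WINDOW_DAYS + 1L) + floor(runif(length(i_ds)) * (o1 - WINDOW_DAYS))
    pieces$distant <- tibble(
      person_id = rep(persons$person_id[i_ds], 2L),
      encounter_date = c(entry[i_ds] - o1, entry[i_ds] - o1 + gap),
      setting = "outpatient",
      dx_group = rep(dx_pool(length(i_ds)), 2L))
  }
  # unrelated-diagnosis noise for a random subset of everyone
  i_no <- which(runif(n) < 0.3 | pattern == "other_only")
  if (length(i_no)) {
    pieces$noise <- tibble(
      person_id = persons$person_id[i_no],
      encounter_date = entry[i_no] - floor(runif(length(i_no)) * (lb + 1)),
      setting = sample(c("inpatient", "outpatient"), length(i_no),
                       replace = TRUE, prob = c(0.2, 0.8)),
      dx_group = "other")
  }

  enc <- dplyr::bind_rows(pieces) |>
    dplyr::arrange(.data$person_id, .data$encounter_date, .data$setting,
                   .data$dx_group)
  attr(enc, "intended_admin_flag") <-
    tibble(person_id = persons$person_id, admin_case_true = flag,
           entry_date = entry) |>
    dplyr::arrange(.data$person_id)
  enc
}

#' Generate the full synthetic dataset in one call
#'
#' Convenience wrapper: [generate_population()], then
#' [simulate_self_report()], then [generate_encounters()].
#'
#' @param config A [sim_config].
#' @return A list with elements `cohort` (both cohorts, flags filled) and
#'   `encounters` (with the `intended_admin_flag` attribute).
#' @export
simulate_study <- function(config = sim_config()) {
  pop <- generate_population(config) |>
    simulate_self_report(config)
  list(cohort = pop, encounters = generate_encounters(pop, config))
}

#' Write / read the synthetic tables as CSV
#'
#' Dates are written ISO-8601 and missing values as empty fields, so the
#' files round-trip exactly.
#'
#' @param cohort,encounters Tibbles from the generator.
#' @param path Output path.
#' @return `path`, invisibly (writers); a tibble (readers).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
write_encounters_csv <- function(encounters, path) {
  utils::write.csv(as.data.frame(encounters), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date_of_birth <- as.Date(df$date_of_birth)
  df$enrollment_date <- as.Date(df$enrollment_date)
  if ("instrument_completed" %in% names(df)) {
    df$instrument_completed <- as.logical(df$instrument_completed)
  }
  as_tibble(df)
}

#' @rdname write_cohort_csv
#' @export
read_encounters_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$encounter_date <- as.Date(df$encounter_date)
  as_tibble(df)
}
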
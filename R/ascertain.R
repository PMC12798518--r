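# Case ascertainment: deterministic linkage/deduplication, the self-report
# (MINI-style) OR-of-modules flag, and the administrative claims case
# definition (>=1 inpatient code OR >=2 outpatient codes within 24 months,
# over a 5-year pre-entry lookback).

MINI_MODULES <- c("mdd", "bipolar", "gad", "social_phobia", "ptsd", "ocd", "panic")

#' Deterministically link two cohorts, keeping the most complete record
#'
#' Persons are matched across cohorts on `person_id` + `date_of_birth`
#' (exact, deterministic linkage). For each duplicate pair the record with
#' the higher `completeness_score` is retained; ties are broken by earlier
#' `enrollment_date`, then by cohort label (A before B). The same
#' `person_id` with conflicting dates of birth is a linkage error.
#'
#' @param cohort_a,cohort_b Cohort tibbles with at least `person_id`,
#'   `date_of_birth`, `enrollment_date`, `cohort_label` and
#'   `completeness_score` columns (see [generate_population()]).
#' @return A tibble with one row per person. The number of excluded
#'   duplicate records is attached as attribute `n_excluded` (and is also
#'   `nrow(a) + nrow(b) - nrow(result)`).
#' @examples
#' cfg <- sim_config(n_cohort_a = 60, n_cohort_b = 40, seed = 7)
#' pop <- generate_population(cfg)
#' linked <- dedup_link(dplyr::filter(pop, cohort_label == "A"),
#'                      dplyr::filter(pop, cohort_label == "B"))
#' attr(linked, "n_excluded")
#' @export
dedup_link <- function(cohort_a, cohort_b) {
  combined <- dplyr::bind_rows(as_tibble(cohort_a), as_tibble(cohort_b))
  for (col in c("person_id", "date_of_birth", "enrollment_date",
                "cohort_label", "completeness_score")) {
    if (!col %in% names(combined)) {
      abort(sprintf("Cohort tables must contain a `%s` column.", col),
            class = "prevbayes_schema_error")
    }
  }
  within_dup <- c(
    cohort_a$person_id[duplicated(cohort_a$person_id)],
    cohort_b$person_id[duplicated(cohort_b$person_id)]
  )
  if (length(within_dup) > 0L) {
    abort(paste0("person_id must be unique within a cohort; duplicated: ",
                 paste(unique(within_dup), collapse = ", ")),
          class = "prevbayes_linkage_error")
  }
  dob_conflicts <- combined |>
    dplyr::distinct(.data$person_id, .data$date_of_birth) |>
    dplyr::count(.data$person_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dob_conflicts) > 0L) {
    abort(paste0("Conflicting date_of_birth for person_id: ",
                 paste(dob_conflicts$person_id, collapse = ", ")),
          class = "prevbayes_linkage_error")
  }
  merged <- combined |>
    dplyr::arrange(.data$person_id,
                   dplyr::desc(.data$completeness_score),
                   .data$enrollment_date,
                   .data$cohort_label) |>
    dplyr::distinct(.data$person_id, .keep_all = TRUE)
  attr(merged, "n_excluded") <- nrow(combined) - nrow(merged)
  merged
}

#' Self-report case flag: OR over diagnostic-instrument modules
#'
#' Combines per-person module indicators from a structured diagnostic
#' instrument into a single mood-and/or-anxiety case flag: a person is a
#' case if any module is positive. The flag is missing only when every
#' module is missing (instrument not administered); a person with some
#' modules observed and none positive is a non-case.
#'
#' Recognised modules: mood (`mdd`, `bipolar`) and anxiety (`gad`,
#' `social_phobia`, `ptsd`, `ocd`, `panic`).
#'
#' @param module_flags A data frame with a `person_id` column and one
#'   0/1/NA column per module.
#' @return A tibble `{person_id, selfreport_case}` with `selfreport_case`
#'   in 0/1/NA.
#' @examples
#' mini_case_flag(tibble::tibble(person_id = c("p1", "p2"),
#'                               mdd = c(0, NA), ptsd = c(1, NA)))
#' @export
mini_case_flag <- function(module_flags) {
  module_flags <- as_tibble(module_flags)
  if (!"person_id" %in% names(module_flags)) {
    abort("`module_flags` must contain a `person_id` column.",
          class = "prevbayes_schema_error")
  }
  mods <- setdiff(names(module_flags), "person_id")
  unknown <- setdiff(mods, MINI_MODULES)
  if (length(unknown) > 0L) {
    abort(paste0("Unknown instrument module(s): ", paste(unknown, collapse = ", "),
                 ". Recognised: ", paste(MINI_MODULES, collapse = ", ")),
          class = "prevbayes_schema_error")
  }
  if (length(mods) == 0L) {
    abort("`module_flags` must contain at least one module column.",
          class = "prevbayes_schema_error")
  }
  m <- as.matrix(module_flags[mods])
  if (!all(m %in% c(0, 1, NA))) {
    abort("Module indicators must be 0, 1 or NA.", class = "prevbayes_schema_error")
  }
  all_missing <- apply(m, 1, function(r) all(is.na(r)))
  any_pos <- apply(m, 1, function(r) any(r == 1, na.rm = TRUE))
  tibble(person_id = module_flags$person_id,
         selfreport_case = dplyr::if_else(all_missing, NA_real_,
                                          as.numeric(any_pos)))
}

# Core of the administrative case rule for one person's in-lookback,
# mood/anxiety encounters: qualify on >=1 inpatient code, or two
# outpatient codes on distinct dates <= 730 days apart.
admin_rule <- function(setting, dates) {
  if (any(setting == "inpatient")) return(1L)
  out_dates <- sort(unique(dates[setting == "outpatient"]))
  if (length(out_dates) >= 2L &&
      any(diff(as.numeric(out_dates)) <= WINDOW_DAYS)) {
    return(1L)
  }
  0L
}

#' Administrative case definition for one person
#'
#' Flags a person as an administrative case if, among their mood/anxiety
#' encounters dated within the lookback window ending at `entry_date`,
#' there is at least one inpatient diagnostic code, or at least two
#' outpatient billing codes on distinct dates no more than 24 months
#' (730 days) apart. The lookback (default 5 years = 1826 days) is
#' inclusive at both ends; encounters after `entry_date` never count.
#'
#' @param encounters Encounter tibble with columns `person_id`,
#'   `encounter_date` (Date), `setting` ("inpatient"/"outpatient") and
#'   `dx_group` ("mood"/"anxiety"/"other").
#' @param person A single `person_id`.
#' @param entry_date Study entry date (Date).
#' @param lookback_years Length of the pre-entry lookback; must be at
#'   least 2 years so the 24-month pairing window fits inside it.
#' @return 0 or 1. An empty encounter set yields 0.
#' @examples
#' enc <- tibble::tibble(person_id = "p1",
#'                       encounter_date = as.Date("2015-06-01"),
#'                       setting = "inpatient", dx_group = "mood")
#' admin_case_flag(enc, "p1", as.Date("2016-01-01"))
#' @export
admin_case_flag <- function(encounters, person, entry_date, lookback_years = 5) {
  if (!is.numeric(lookback_years) || lookback_years * 12 < 24) {
    abort("`lookback_years` must cover at least the 24-month pairing window.",
          class = "prevbayes_config_error")
  }
  encounters <- as_tibble(encounters)
  entry_date <- as.Date(entry_date)
  lb_start <- entry_date - days_per_lookback(lookback_years)
  e <- encounters |>
    dplyr::filter(.data$person_id == person,
                  .data$dx_group %in% c("mood", "anxiety"),
                  .data$encounter_date >= lb_start,
                  .data$encounter_date <= entry_date)
  if (nrow(e) == 0L) return(0L)
  admin_rule(e$setting, as.Date(e$encounter_date))
}

#' Administrative case flags for a whole cohort
#'
#' Vectorised form of [admin_case_flag()]: applies the administrative case
#' definition to every person in `cohort`, using each person's
#' `enrollment_date` as the study entry date.
#'
#' @inheritParams admin_case_flag
#' @param cohort A cohort tibble with `person_id` and `enrollment_date`
#'   columns, one row per person (deduplicate first with [dedup_link()]).
#' @return A tibble `{person_id, admin_case}`.
#' @export
admin_case_flags <- function(encounters, cohort, lookback_years = 5) {
  if (!is.numeric(lookback_years) || lookback_years * 12 < 24) {
    abort("`lookback_years` must cover at least the 24-month pairing window.",
          class = "prevbayes_config_error")
  }
  cohort <- as_tibble(cohort)
  if (anyDuplicated(cohort$person_id)) {
    abort("`cohort` must have one row per person; run dedup_link() first.",
          class = "prevbayes_schema_error")
  }
  encounters <- as_tibble(encounters) |>
    dplyr::filter(.data$dx_group %in% c("mood", "anxiety"))
  lb_days <- days_per_lookback(lookback_years)
  entry <- as.Date(cohort$enrollment_date)
  names(entry) <- cohort$person_id
  flags <- encounters |>
    dplyr::mutate(entry_date = entry[.data$person_id]) |>
    dplyr::filter(!is.na(.data$entry_date),
                  .data$encounter_date >= .data$entry_date - lb_days,
                  .data$encounter_date <= .data$entry_date) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(admin_case = admin_rule(.data$setting,
                                             as.Date(.data$encounter_date)),
                     .groups = "drop")
  cohort |>
    dplyr::select("person_id") |>
    dplyr::left_join(flags, by = "person_id") |>
    dplyr::mutate(admin_case = dplyr::coalesce(.data$admin_case, 0L))
}

#' Combined per-person case flags from both sources
#'
#' Assembles the per-person flag table used downstream: the self-report
#' flag already on the cohort table (missing for instrument
#' non-completers) and the administrative flag from the claims algorithm
#' (defined for every linked person).
#'
#' @inheritParams admin_case_flags
#' @return A tibble `{person_id, selfreport_case, admin_case}`.
#' @export
case_flags <- function(cohort, encounters, lookback_years = 5) {
  cohort <- as_tibble(cohort)
  if (!"selfreport_flag" %in% names(cohort)) {
    abort("`cohort` must contain a `selfreport_flag` column (see simulate_self_report()).",
          class = "prevbayes_schema_error")
  }
  admin <- admin_case_flags(encounters, cohort, lookback_years)
  cohort |>
    dplyr::transmute(person_id = .data$person_id,
                     selfreport_case = as.numeric(.data$selfreport_flag)) |>
    dplyr::left_join(admin, by = "person_id")
}

#' Count cases for one ascertainment source
#'
#' Reduces a per-person flag table to the `(n, k)` sufficient statistic
#' for one source. For the self-report source, persons with a missing flag
#' (instrument not completed) are dropped and the drop count is attached
#' as attribute `n_dropped`; the administrative flag is defined for
#' everyone.
#'
#' @param flags A tibble from [case_flags()] (or with the relevant
#'   `*_case` column).
#' @param source `"selfreport"` or `"admin"`.
#' @param label Source label for the resulting [count_data]; defaults to
#'   the source name.
#' @return A [count_data] object.
#' @examples
#' case_counts(tibble::tibble(person_id = 1:4,
#'                            selfreport_case = c(1, 0, NA, 1)),
#'             "selfreport")
#' @export
case_counts <- function(flags, source = c("selfreport", "admin"), label = NULL) {
  source <- match.arg(source)
  col <- paste0(source, "_case")
  flags <- as_tibble(flags)
  if (!col %in% names(flags)) {
    abort(sprintf("`flags` must contain a `%s` column.", col),
          class = "prevbayes_schema_error")
  }
  v <- flags[[col]]
  n_dropped <- sum(is.na(v))
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    abort("No persons remain after dropping missing flags.",
          class = "prevbayes_empty_source_error")
  }
  out <- count_data(length(v), sum(v == 1), label %||% source)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write per-person case flags as CSV
#'
#' @param flags Tibble from [case_flags()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flags_csv <- function(flags, path) {
  utils::write.csv(as.data.frame(flags), path, row.names = FALSE, na = "")
  invisible(path)
}
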
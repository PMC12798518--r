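# The synthetic linked-cohort generator: determinism, calibration of the
# misclassification overlays, duplicate injection, and exact consistency
# between generated encounters and the claims algorithm.

test_that("identical configurations produce bit-identical tables and CSVs", {
  cfg <- sim_config(n_cohort_a = 80, n_cohort_b = 50, seed = 123)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(as.data.frame(s1$encounters), as.data.frame(s2$encounters))
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cohort_csv(s1$cohort, f1)
  write_cohort_csv(s2$cohort, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("degenerate prevalence yields an all-negative population", {
  cfg <- sim_config(true_prevalence = 0, n_cohort_a = 100, n_cohort_b = 10,
                    duplicate_rate = 0, seed = 5)
  pop <- generate_population(cfg)
  expect_true(all(pop$true_status == 0L))
})

test_that("sampled prevalence concentrates around the configured truth", {
  cfg <- sim_config(true_prevalence = 0.59, n_cohort_a = 10000,
                    n_cohort_b = 10, duplicate_rate = 0, seed = 11)
  pop <- generate_population(cfg)
  a <- dplyr::filter(pop, cohort_label == "A")
  expect_lt(abs(mean(a$true_status) - 0.59),
            3 * sqrt(0.59 * 0.41 / 10000))
})

test_that("perfect instruments reproduce the true status exactly", {
  cfg <- sim_config(n_cohort_a = 200, n_cohort_b = 60,
                    selfreport_sens = 1, selfreport_spec = 1,
                    admin_sens = 1, admin_spec = 1,
                    instrument_completion_rate = 1, seed = 9)
  s <- simulate_study(cfg)
  completers <- dplyr::filter(s$cohort, instrument_completed)
  expect_equal(completers$selfreport_flag, as.numeric(completers$true_status))

  linked <- dedup_link(dplyr::filter(s$cohort, cohort_label == "A"),
                       dplyr::filter(s$cohort, cohort_label == "B"))
  fl <- admin_case_flags(s$encounters, linked, cfg$lookback_years)
  joined <- dplyr::inner_join(fl, dplyr::select(linked, person_id, true_status),
                              by = "person_id")
  expect_equal(joined$admin_case, joined$true_status)
})

test_that("apparent prevalence matches sens * pi + (1 - spec) * (1 - pi)", {
  n <- 50000
  cfg <- sim_config(true_prevalence = 0.57, n_cohort_a = n, n_cohort_b = 10,
                    duplicate_rate = 0, instrument_completion_rate = 1,
                    selfreport_sens = 0.95, selfreport_spec = 0.84,
                    admin_sens = 0.629, admin_spec = 0.938, seed = 21)
  s <- simulate_study(cfg)
  a <- dplyr::filter(s$cohort, cohort_label == "A")

  expected_sr <- 0.95 * 0.57 + 0.16 * 0.43     # 0.6103
  obs_sr <- mean(a$selfreport_flag)
  expect_lt(abs(obs_sr - expected_sr), 3 * sqrt(expected_sr * (1 - expected_sr) / n))

  expected_ad <- 0.629 * 0.57 + 0.062 * 0.43   # 0.3852
  linked <- dedup_link(a, dplyr::filter(s$cohort, cohort_label == "B"))
  fl <- admin_case_flags(s$encounters, linked, cfg$lookback_years)
  obs_ad <- mean(fl$admin_case[fl$person_id %in% a$person_id])
  expect_lt(abs(obs_ad - expected_ad), 3 * sqrt(expected_ad * (1 - expected_ad) / n))
})

test_that("instrument completion matches the configured rate in expectation", {
  cfg <- sim_config(n_cohort_a = 1061, n_cohort_b = 10, duplicate_rate = 0,
                    instrument_completion_rate = 549 / 1061, seed = 33)
  pop <- generate_population(cfg)
  n_completers <- sum(pop$instrument_completed)
  se <- sqrt(1061 * (549 / 1061) * (1 - 549 / 1061))
  expect_lt(abs(n_completers - 549), 3 * se)
})

test_that("exactly the configured number of persons appear in both cohorts", {
  cfg <- sim_config(n_cohort_a = 150, n_cohort_b = 90,
                    duplicate_rate = 0.2, seed = 13)
  pop <- generate_population(cfg)
  shared <- intersect(pop$person_id[pop$cohort_label == "A"],
                      pop$person_id[pop$cohort_label == "B"])
  expect_equal(length(shared), round(0.2 * 150))
  # duplicated persons carry different completeness scores per cohort
  dup_scores <- pop |>
    dplyr::filter(person_id %in% shared) |>
    dplyr::count(person_id, completeness_score)
  expect_true(all(dup_scores$n == 1L))
})

test_that("generated encounters reproduce the intended flags for random configs", {
  set.seed(99)
  for (i in 1:8) {
    cfg <- sim_config(
      true_prevalence = runif(1, 0.1, 0.9),
      n_cohort_a = sample(50:250, 1),
      n_cohort_b = sample(30:150, 1),
      duplicate_rate = runif(1, 0, 0.3),
      admin_sens = runif(1, 0.5, 1),
      admin_spec = runif(1, 0.5, 1),
      lookback_years = sample(3:6, 1),
      seed = sample.int(1e6, 1))
    s <- simulate_study(cfg)
    intent <- attr(s$encounters, "intended_admin_flag")
    linked <- dedup_link(dplyr::filter(s$cohort, cohort_label == "A"),
                         dplyr::filter(s$cohort, cohort_label == "B"))
    fl <- admin_case_flags(s$encounters, linked, cfg$lookback_years)
    joined <- dplyr::inner_join(fl, intent, by = "person_id")
    expect_equal(nrow(joined), nrow(linked))
    expect_identical(sum(joined$admin_case != joined$admin_case_true), 0L,
                     info = sprintf("config %d", i))
  }
})

test_that("encounters never post-date the linked person's enrollment", {
  s <- simulate_study(sim_config(n_cohort_a = 120, n_cohort_b = 80, seed = 55))
  intent <- attr(s$encounters, "intended_admin_flag")
  joined <- dplyr::inner_join(s$encounters, intent, by = "person_id")
  expect_true(all(joined$encounter_date <= joined$entry_date))
})

test_that("cohort tables round-trip through CSV", {
  s <- simulate_study(sim_config(n_cohort_a = 40, n_cohort_b = 25, seed = 3))
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(s$cohort, f)
  back <- read_cohort_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(s$cohort))
  fe <- tempfile(fileext = ".csv")
  write_encounters_csv(s$encounters, fe)
  back_e <- read_encounters_csv(fe)
  expect_equal(as.data.frame(back_e),
               as.data.frame(tibble::as_tibble(s$encounters)),
               ignore_attr = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(true_prevalence = 1.2), class = "prevbayes_config_error")
  expect_error(sim_config(n_cohort_a = 0), class = "prevbayes_config_error")
  expect_error(sim_config(lookback_years = 1), class = "prevbayes_config_error")
  expect_error(sim_config(duplicate_rate = 1, n_cohort_a = 100, n_cohort_b = 50),
               class = "prevbayes_config_error")
})
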
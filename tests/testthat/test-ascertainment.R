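# Deterministic linkage, the self-report OR-of-modules flag, and the
# administrative claims case algorithm.

test_that("disjoint cohorts merge without exclusions", {
  a <- dplyr::bind_rows(lapply(sprintf("A%02d", 1:10), person_row))
  b <- dplyr::bind_rows(lapply(sprintf("B%02d", 1:5), person_row,
                               cohort = "B"))
  m <- dedup_link(a, b)
  expect_equal(nrow(m), 15L)
  expect_identical(attr(m, "n_excluded"), 0L)
})

test_that("duplicates resolve to the most complete record with stated tie-breaks", {
  a <- person_row("P1", "A", score = 7, enroll = "2015-06-01")
  b <- person_row("P1", "B", score = 4, enroll = "2019-06-01")
  m <- dedup_link(a, b)
  expect_equal(nrow(m), 1L)
  expect_identical(m$completeness_score, 7)
  expect_identical(attr(m, "n_excluded"), 1L)

  # completeness tie: earlier enrollment wins
  b2 <- person_row("P1", "B", score = 7, enroll = "2013-01-01")
  expect_identical(dedup_link(a, b2)$cohort_label, "B")

  # full tie: cohort A wins
  b3 <- person_row("P1", "B", score = 7, enroll = "2015-06-01")
  expect_identical(dedup_link(a, b3)$cohort_label, "A")
})

test_that("linkage is idempotent and respects |A| + |B| - duplicates", {
  cfg <- sim_config(n_cohort_a = 120, n_cohort_b = 80,
                    duplicate_rate = 0.25, seed = 31)
  pop <- generate_population(cfg)
  a <- dplyr::filter(pop, cohort_label == "A")
  b <- dplyr::filter(pop, cohort_label == "B")
  m <- dedup_link(a, b)
  expect_equal(nrow(m), nrow(a) + nrow(b) - cfg$n_duplicates)
  m2 <- dedup_link(dplyr::filter(m, cohort_label == "A"),
                   dplyr::filter(m, cohort_label == "B"))
  expect_equal(dplyr::arrange(m2, person_id), dplyr::arrange(m, person_id),
               ignore_attr = TRUE)
})

test_that("conflicting dates of birth are a linkage error naming the ids", {
  a <- person_row("P1", "A", dob = "1980-01-01")
  b <- person_row("P1", "B", dob = "1981-05-05")
  expect_error(dedup_link(a, b), "P1", class = "prevbayes_linkage_error")
})

test_that("self-report case flag is an OR over instrument modules", {
  flags <- mini_case_flag(tibble::tibble(
    person_id = c("p1", "p2", "p3", "p4"),
    mdd = c(0, 0, NA, NA),
    ptsd = c(0, 1, NA, 0),
    gad = c(0, 0, NA, NA)))
  expect_equal(flags$selfreport_case, c(0, 1, NA, 0))
  expect_error(mini_case_flag(tibble::tibble(person_id = "p", psychosis = 1)),
               "psychosis", class = "prevbayes_schema_error")
})

test_that("a module-positive fixture reproduces the completer counts", {
  fix <- tibble::tibble(person_id = sprintf("p%03d", 1:549),
                        mdd = rep(c(1, 0), c(311, 238)))
  flags <- mini_case_flag(fix)
  counts <- case_counts(dplyr::rename(flags, selfreport_case = selfreport_case),
                        "selfreport", label = "completers")
  expect_equal(c(counts$n, counts$k), c(549L, 311L))
  expect_equal(100 * counts$k / counts$n, 56.6, tolerance = 0.05)
})

test_that("drop count plus retained persons equals total persons", {
  flags <- tibble::tibble(person_id = 1:10,
                          selfreport_case = c(1, 0, NA, 1, NA, 0, 1, NA, 0, 1))
  counts <- case_counts(flags, "selfreport")
  expect_equal(counts$n + attr(counts, "n_dropped"), 10L)
  expect_error(case_counts(tibble::tibble(person_id = 1,
                                          selfreport_case = NA_real_),
                           "selfreport"),
               class = "prevbayes_empty_source_error")
})

test_that("administrative rule follows the inpatient/outpatient case definition", {
  entry <- as.Date("2016-01-01")
  # no encounters
  expect_identical(admin_case_flag(enc_row("p", entry)[0, ], "p", entry), 0L)
  # one inpatient mood code three years before entry qualifies
  expect_identical(
    admin_case_flag(enc_row("p", entry - 3 * 365, "inpatient"), "p", entry), 1L)
  # two outpatient codes 731 days apart never qualify
  e <- dplyr::bind_rows(enc_row("p", entry - 1000),
                        enc_row("p", entry - 1000 + 731))
  expect_identical(admin_case_flag(e, "p", entry), 0L)
  # exactly 730 days apart qualifies (window inclusive)
  e730 <- dplyr::bind_rows(enc_row("p", entry - 1000),
                           enc_row("p", entry - 1000 + 730))
  expect_identical(admin_case_flag(e730, "p", entry), 1L)
  # both encounters outside the five-year lookback
  far <- dplyr::bind_rows(enc_row("p", entry - round(6 * 365.25)),
                          enc_row("p", entry - round(5.5 * 365.25)))
  expect_identical(admin_case_flag(far, "p", entry), 0L)
  # two same-day outpatient claims are one visit, not a qualifying pair
  same <- dplyr::bind_rows(enc_row("p", entry - 100),
                           enc_row("p", entry - 100, dx = "anxiety"))
  expect_identical(admin_case_flag(same, "p", entry), 0L)
  # unrelated diagnosis groups never count
  expect_identical(
    admin_case_flag(enc_row("p", entry - 10, "inpatient", dx = "other"),
                    "p", entry), 0L)
  # lookback boundary is inclusive
  boundary <- dplyr::bind_rows(enc_row("p", entry - 1826),
                               enc_row("p", entry - 1826 + 700))
  expect_identical(admin_case_flag(boundary, "p", entry), 1L)
})

test_that("administrative flag agrees with a brute-force pair-enumeration oracle", {
  set.seed(77)
  entry <- as.Date("2016-01-01")
  for (i in 1:60) {
    enc <- random_encounters("p", entry, sample(0:8, 1))
    expect_identical(admin_case_flag(enc, "p", entry),
                     admin_oracle(enc, "p", entry),
                     info = sprintf("case %d", i))
  }
})

test_that("adding an encounter never revokes a positive administrative flag", {
  set.seed(78)
  entry <- as.Date("2016-01-01")
  for (i in 1:30) {
    enc <- random_encounters("p", entry, sample(1:6, 1))
    before <- admin_case_flag(enc, "p", entry)
    extra <- random_encounters("p", entry, 1)
    after <- admin_case_flag(dplyr::bind_rows(enc, extra), "p", entry)
    expect_gte(after, before)
  }
})

test_that("a lookback shorter than the pairing window is rejected", {
  expect_error(admin_case_flag(enc_row("p", "2015-01-01"), "p",
                               as.Date("2016-01-01"), lookback_years = 1),
               class = "prevbayes_config_error")
})
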
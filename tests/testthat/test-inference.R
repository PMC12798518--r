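# Conjugate posterior arithmetic, the marginal likelihood, posterior
# summaries and the frequentist comparison.

test_that("conjugate updating adds the data counts to the prior", {
  post <- conjugate_posterior(noninformative_prior(), count_data(549, 311))
  expect_equal(c(post$alpha, post$beta), c(312, 239))
  post2 <- conjugate_posterior(beta_params(633, 430), count_data(549, 311))
  expect_equal(c(post2$alpha, post2$beta), c(944, 668))
  expect_equal(beta_stats(post2)$mean, 944 / 1612, tolerance = 1e-12)
})

test_that("log evidence matches closed forms and quadrature", {
  expect_equal(log_evidence(noninformative_prior(), count_data(1, 1)),
               log(1 / 2), tolerance = 1e-12)
  expect_equal(log_evidence(noninformative_prior(), count_data(2, 1)),
               log(1 / 6), tolerance = 1e-12)
  le <- log_evidence(beta_params(633, 430), count_data(549, 311))
  oracle <- log_evidence_quadrature(633, 430, 549, 311)
  expect_equal(le, oracle, tolerance = 1e-8)
})

test_that("posterior summaries carry exact quantiles and the percent convention", {
  res <- posterior_summary(beta_params(312, 239))
  expect_equal(res$estimate, 312 / 551, tolerance = 1e-12)
  expect_equal(res$lower, qbeta(0.025, 312, 239))
  expect_equal(res$upper, qbeta(0.975, 312, 239))
  expect_identical(res$formatted$estimate, "57.0%")
  expect_identical(res$formatted$interval, "(52.0%, 61.0%)")
  expect_identical(res$interval_type, "CrI")

  res2 <- posterior_summary(beta_params(2338, 1643))
  expect_equal(res2$estimate, 2338 / 3981, tolerance = 1e-12)
  expect_identical(res2$formatted$estimate, "59.0%")

  res3 <- posterior_summary(beta_params(1, 1))
  expect_equal(c(res3$estimate, res3$lower, res3$upper), c(0.5, 0.025, 0.975))
})

test_that("frequentist estimate is the proportion with a Wald interval", {
  res <- frequentist_prevalence(count_data(549, 311))
  expect_equal(res$estimate, 311 / 549, tolerance = 1e-12)
  expect_equal(res$se, sqrt((311 / 549) * (238 / 549) / 549), tolerance = 1e-12)
  expect_identical(res$formatted$estimate, "56.6%")
  expect_identical(res$formatted$interval, "(52.5%, 60.8%)")
  expect_identical(res$formatted$se, "0.021")
  expect_identical(res$interval_type, "CI")

  res2 <- frequentist_prevalence(count_data(100, 50))
  expect_identical(res2$formatted$estimate, "50.0%")
  expect_identical(res2$formatted$interval, "(40.2%, 59.8%)")
})

test_that("frequentist estimate agrees with an identity-link binomial GLM", {
  fit <- stats::glm(cbind(311, 238) ~ 1, family = binomial(link = "identity"),
                    start = 0.5)
  res <- frequentist_prevalence(count_data(549, 311))
  expect_equal(unname(coef(fit)), res$estimate, tolerance = 1e-8)
  expect_equal(unname(sqrt(vcov(fit)[1, 1])), res$se, tolerance = 1e-6)
})

test_that("boundary counts yield a flagged degenerate interval, not an error", {
  expect_warning(res <- frequentist_prevalence(count_data(10, 10)),
                 "degenerate")
  expect_equal(res$estimate, 1)
  expect_equal(res$se, 0)
  expect_true(res$degenerate)
})

test_that("the posterior mean lies between the prior mean and the data proportion", {
  set.seed(402)
  for (i in 1:20) {
    prior <- beta_params(runif(1, 1, 200), runif(1, 1, 200))
    n <- sample(10:500, 1)
    k <- sample(0:n, 1)
    prior_mean <- prior$alpha / (prior$alpha + prior$beta)
    post_mean <- beta_stats(conjugate_posterior(prior, count_data(n, k)))$mean
    bounds <- sort(c(prior_mean, k / n))
    if (bounds[1] < bounds[2]) {
      expect_gt(post_mean, bounds[1])
      expect_lt(post_mean, bounds[2])
    }
  }
})

test_that("the data dominate the prior as the sample grows", {
  prior <- beta_params(633, 430)
  target <- 311 / 549
  err <- vapply(c(1, 10, 100, 1000), function(m) {
    post <- conjugate_posterior(prior, count_data(549 * m, 311 * m))
    abs(beta_stats(post)$mean - target)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[4], 1e-3)
})

test_that("credible intervals nest by level", {
  post <- beta_params(944, 668)
  s90 <- beta_stats(post, 0.90)
  s95 <- beta_stats(post, 0.95)
  expect_gt(s90$lower, s95$lower)
  expect_lt(s90$upper, s95$upper)
})

test_that("the flat-prior posterior mean is (k + 1) / (n + 2) exactly", {
  for (nk in list(c(10, 3), c(549, 311), c(1000, 999))) {
    post <- conjugate_posterior(noninformative_prior(),
                                count_data(nk[1], nk[2]))
    expect_equal(beta_stats(post)$mean, (nk[2] + 1) / (nk[1] + 2),
                 tolerance = 1e-12)
  }
})

test_that("flat-prior Bayesian and frequentist analyses agree for large n", {
  for (nk in list(c(549, 311), c(1000, 380), c(5000, 2950))) {
    n <- nk[1]; k <- nk[2]
    bayes <- posterior_summary(conjugate_posterior(noninformative_prior(),
                                                   count_data(n, k)))
    freq <- frequentist_prevalence(count_data(n, k))
    expect_lte(abs(bayes$estimate - k / n), 2 / n)
    expect_lt(abs(bayes$lower - freq$lower), 0.005)
    expect_lt(abs(bayes$upper - freq$upper), 0.005)
  }
})
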
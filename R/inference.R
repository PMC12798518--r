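#' Exact conjugate posterior under the beta-Bernoulli model
#'
#' With a Beta(alpha, beta) prior on the prevalence and k cases among n
#' independent Bernoulli observations, the posterior is
#' Beta(alpha + k, beta + n - k). This closed form is the oracle against
#' which the MCMC sampler is validated.
#'
#' @param prior A [beta_params] prior.
#' @param data A [count_data] object with the likelihood counts.
#' @return A [beta_params] posterior, labelled "posterior(prior | data)".
#' @examples
#' conjugate_posterior(elicit_prior(count_data(1061, 632)),
#'                     count_data(549, 311))
#' @export
conjugate_posterior <- function(prior, data) {
  stopifnot(inherits(prior, "beta_params"))
  data <- as_count_data(data)
  beta_params(prior$alpha + data$k, prior$beta + data$n - data$k,
              sprintf("posterior(%s | %s)", prior$label, data$label))
}

#' Log marginal likelihood of an ordered Bernoulli sequence
#'
#' The evidence P(D) for k successes among n ordered Bernoulli trials under
#' a Beta(alpha, beta) prior: `B(alpha + k, beta + n - k) / B(alpha, beta)`,
#' computed in log space (no binomial coefficient, since the data are an
#' ordered sequence rather than a binomial count).
#'
#' @inheritParams conjugate_posterior
#' @return The log evidence (a single number, always finite).
#' @examples
#' exp(log_evidence(noninformative_prior(), count_data(1, 1)))  # 1/2
#' @export
log_evidence <- function(prior, data) {
  stopifnot(inherits(prior, "beta_params"))
  data <- as_count_data(data)
  lbeta(prior$alpha + data$k, prior$beta + data$n - data$k) -
    lbeta(prior$alpha, prior$beta)
}

new_prevalence_result <- function(method, estimate, lower, upper, se,
                                  interval_type, level, extra = list()) {
  fmt <- if (identical(interval_type, "CI")) format_percent_freq else format_percent_bayes
  se_fmt <- if (identical(interval_type, "CI")) sprintf("%.3f", round(se, 3)) else sprintf("%.2f", round(se, 2))
  structure(
    c(list(method = method, estimate = estimate, lower = lower, upper = upper,
           se = se, interval_type = interval_type, level = level,
           formatted = list(
             estimate = fmt(estimate),
             interval = sprintf("(%s, %s)", fmt(lower), fmt(upper)),
             se = se_fmt)),
      extra),
    class = "prevalence_result")
}

#' @export
print.prevalence_result <- function(x, ...) {
  cat(sprintf("<prevalence_result> %s: %s %s %s, SE %s\n",
              x$method, x$formatted$estimate,
              if (x$interval_type == "CI") "CI" else "CrI",
              x$formatted$interval, x$formatted$se))
  if (isTRUE(x$degenerate)) cat("  (boundary data: degenerate interval)\n")
  invisible(x)
}

#' @rdname tidy.beta_params
#' @method tidy prevalence_result
#' @export
tidy.prevalence_result <- function(x, ...) {
  tibble(method = x$method, estimate = x$estimate, lower = x$lower,
         upper = x$upper, se = x$se, interval_type = x$interval_type,
         level = x$level)
}

#' Summarise a beta posterior as a prevalence result
#'
#' Posterior mean, posterior standard deviation (reported in the SE column)
#' and the exact equal-tailed credible interval from the beta quantile
#' function. The formatted percent strings follow the reporting convention:
#' the probability is rounded to two decimals, then printed as a percent
#' with one decimal.
#'
#' @param post A [beta_params] posterior.
#' @param level Credible level, default 0.95.
#' @return A `prevalence_result` (method "conjugate", interval type "CrI").
#' @examples
#' posterior_summary(beta_params(944, 668))
#' @export
posterior_summary <- function(post, level = 0.95) {
  s <- beta_stats(post, level)
  new_prevalence_result("conjugate", s$mean, s$lower, s$upper, s$sd,
                        "CrI", level, extra = list(posterior = post))
}

#' Frequentist prevalence estimate with Wald confidence interval
#'
#' The maximum-likelihood estimate of an intercept-only identity-link
#' binomial model is the sample proportion `k / n`; its standard error is
#' `sqrt(p(1-p)/n)` and the Wald interval is `p +/- z * se` (z = 1.959964
#' for a 95% interval), truncated to `[0, 1]`.
#'
#' At the boundary (`k = 0` or `k = n`) the Wald interval is degenerate
#' (`se = 0`); the estimate is returned with a `degenerate = TRUE` flag and
#' a warning rather than an error.
#'
#' @param data A [count_data] object.
#' @param level Confidence level, default 0.95.
#' @return A `prevalence_result` (method "frequentist", interval type "CI").
#' @examples
#' frequentist_prevalence(count_data(549, 311))
#' @export
frequentist_prevalence <- function(data, level = 0.95) {
  data <- as_count_data(data)
  check_prob(level, "level", allow_zero_one = FALSE)
  p <- data$k / data$n
  se <- sqrt(p * (1 - p) / data$n)
  z <- if (identical(level, 0.95)) Z_975 else qnorm(1 - (1 - level) / 2)
  lower <- max(0, p - z * se)
  upper <- min(1, p + z * se)
  degenerate <- data$k == 0L || data$k == data$n
  if (degenerate) {
    warn("Boundary data (k = 0 or k = n): Wald interval is degenerate (se = 0).")
  }
  new_prevalence_result("frequentist", p, lower, upper, se, "CI", level,
                        extra = list(data = data, degenerate = degenerate))
}
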
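# Internal validators and formatting helpers.

check_prob <- function(x, name, allow_zero_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name), class = "prevbayes_config_error")
  }
  ok <- if (allow_zero_one) x >= 0 && x <= 1 else x > 0 && x < 1
  if (!ok) {
    abort(sprintf("`%s` must be a probability in %s, got %s.",
                  name, if (allow_zero_one) "[0, 1]" else "(0, 1)", format(x)),
          class = "prevbayes_config_error")
  }
  invisible(x)
}

check_count <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x)) {
    abort(sprintf("`%s` must be a single whole number.", name),
          class = "prevbayes_config_error")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive, got %s.", name, format(x)),
          class = "prevbayes_config_error")
  }
  invisible(as.integer(x))
}

# Wald z at the 97.5th percentile, fixed for bit-stable intervals.
Z_975 <- 1.959964

# 24-month outpatient pairing window and 5-year lookback, in whole days.
# 730 days = two 365-day years; 1826 days = 5 years incl. one leap day.
WINDOW_DAYS <- 730L
days_per_lookback <- function(lookback_years) as.integer(round(lookback_years * 365.25))

# Reporting convention for Bayesian rows: summarise the probability to two
# decimals, then print as a percent with one decimal (0.585.. -> "59.0%").
format_percent_bayes <- function(x) sprintf("%.1f%%", 100 * round(x, 2))

# Frequentist rows print the percent to one decimal directly.
format_percent_freq <- function(x) sprintf("%.1f%%", 100 * x)

# Deterministic per-chain seed derived from the master seed; kept < 2^31.
chain_seed <- function(master_seed, chain) {
  as.integer((abs(as.numeric(master_seed)) * 48271 + chain * 104729) %% 2147483646) + 1L
}
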
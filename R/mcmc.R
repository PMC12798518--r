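#' MCMC sampler settings
#'
#' Settings for the adaptive random-walk Metropolis sampler. `iterations`
#' counts all draws per chain including warm-up; after discarding the first
#' `warmup` draws, every `thin`-th draw is retained, so each chain keeps
#' `floor((iterations - warmup) / thin)` draws.
#'
#' @param iterations Total iterations per chain (including warm-up).
#' @param chains Number of independent chains.
#' @param warmup Warm-up iterations discarded from the front of each chain;
#'   the proposal scale adapts only during warm-up.
#' @param thin Keep every `thin`-th post-warm-up draw.
#' @param seed Master seed; each chain is seeded deterministically from
#'   `(seed, chain index)`.
#' @param proposal_scale Initial random-walk standard deviation on the
#'   logit scale (adapted during warm-up toward 44% acceptance).
#' @return An object of class `mcmc_settings`.
#' @examples
#' mcmc_settings()  # 20,000 iterations, 4 chains, warm-up 500, thin 5
#' @export
mcmc_settings <- function(iterations = 20000, chains = 4, warmup = 500,
                          thin = 5, seed = 123, proposal_scale = 0.5) {
  iterations <- check_count(iterations, "iterations")
  chains <- check_count(chains, "chains")
  warmup <- check_count(warmup, "warmup", positive = FALSE)
  thin <- check_count(thin, "thin")
  if (warmup < 0 || iterations <= warmup) {
    abort("`iterations` must exceed `warmup` (and warmup >= 0).",
          class = "prevbayes_config_error")
  }
  retained <- (iterations - warmup) %/% thin
  if (retained < 1L) {
    abort("Settings retain no draws: floor((iterations - warmup) / thin) < 1.",
          class = "prevbayes_config_error")
  }
  if (!is.numeric(proposal_scale) || proposal_scale <= 0) {
    abort("`proposal_scale` must be positive.", class = "prevbayes_config_error")
  }
  structure(list(iterations = iterations, chains = chains, warmup = warmup,
                 thin = thin, seed = as.integer(seed),
                 proposal_scale = proposal_scale, retained = retained),
            class = "mcmc_settings")
}

#' @export
print.mcmc_settings <- function(x, ...) {
  cat(sprintf("<mcmc_settings> %d chains x %d iterations (warm-up %d, thin %d) -> %d retained/chain, seed %d\n",
              x$chains, x$iterations, x$warmup, x$thin, x$retained, x$seed))
  invisible(x)
}

# One adaptive random-walk Metropolis chain on eta = logit(theta).
# Target: posterior Beta(a, b) density in theta times the Jacobian
# d(theta)/d(eta) = theta (1 - theta), i.e.
#   log f(eta) = -a log(1 + exp(-eta)) - b log(1 + exp(eta)).
# Robbins-Monro adaptation of log(scale) toward 0.44 acceptance during
# warm-up; the scale is frozen afterwards so the retained chain is Markovian.
run_rwm_chain <- function(a, b, settings, chain_index) {
  set.seed(chain_seed(settings$seed, chain_index))
  n_iter <- settings$iterations
  log_target <- function(eta) -a * log1p(exp(-eta)) - b * log1p(exp(eta))

  eta <- qlogis(runif(1, 0.05, 0.95))  # over-dispersed start
  lt <- log_target(eta)
  log_scale <- log(settings$proposal_scale)
  zs <- rnorm(n_iter)
  us <- runif(n_iter)

  retained <- numeric(settings$retained)
  n_keep <- 0L
  acc_post <- 0L
  for (i in seq_len(n_iter)) {
    prop <- eta + exp(log_scale) * zs[i]
    lt_prop <- log_target(prop)
    log_ratio <- lt_prop - lt
    accept <- log(us[i]) < log_ratio
    if (accept) {
      eta <- prop
      lt <- lt_prop
    }
    if (i <= settings$warmup) {
      # stochastic approximation step toward 44% acceptance
      alpha_i <- min(1, exp(log_ratio))
      log_scale <- log_scale + i^(-0.6) * (alpha_i - 0.44)
    } else {
      if (accept) acc_post <- acc_post + 1L
      j <- i - settings$warmup
      if (j %% settings$thin == 0L && n_keep < settings$retained) {
        n_keep <- n_keep + 1L
        retained[n_keep] <- eta
      }
    }
  }
  list(draws = plogis(retained[seq_len(n_keep)]),
       acceptance = acc_post / (n_iter - settings$warmup),
       scale = exp(log_scale))
}

#' Sample the posterior prevalence by adaptive random-walk Metropolis
#'
#' Draws from the posterior of the beta-Bernoulli model (beta prior, k
#' cases among n Bernoulli observations) with one adaptive random-walk
#' Metropolis chain per requested chain, proposing on the logit scale with
#' the appropriate Jacobian so the target on the prevalence scale is
#' exactly the Beta(alpha + k, beta + n - k) posterior. Because that
#' posterior is available in closed form, every run can be validated
#' against [conjugate_posterior()].
#'
#' @inheritParams conjugate_posterior
#' @param settings An [mcmc_settings] object.
#' @return A `chain_set`: retained draws (matrix, one column per chain, all
#'   strictly inside (0, 1)), the settings, per-chain acceptance rates, and
#'   the exact conjugate posterior for reference.
#' @examples
#' cs <- mcmc_sample(noninformative_prior(), count_data(50, 30),
#'                   mcmc_settings(2000, chains = 2, warmup = 200, thin = 1))
#' colMeans(cs$draws)
#' @export
mcmc_sample <- function(prior, data, settings = mcmc_settings()) {
  stopifnot(inherits(prior, "beta_params"), inherits(settings, "mcmc_settings"))
  data <- as_count_data(data)
  a <- prior$alpha + data$k
  b <- prior$beta + data$n - data$k
  chains <- lapply(seq_len(settings$chains), function(c_i) {
    run_rwm_chain(a, b, settings, c_i)
  })
  acc <- vapply(chains, `[[`, numeric(1), "acceptance")
  if (any(acc == 0)) {
    abort("Sampler failure: a chain rejected every post-warm-up proposal.",
          class = "prevbayes_sampler_error")
  }
  draws <- vapply(chains, `[[`, numeric(settings$retained), "draws")
  draws <- matrix(draws, nrow = settings$retained, ncol = settings$chains)
  structure(list(draws = draws, settings = settings, acceptance_rate = acc,
                 posterior = conjugate_posterior(prior, data)),
            class = "chain_set")
}

#' @export
print.chain_set <- function(x, ...) {
  cat(sprintf("<chain_set> %d chains x %d retained draws (acceptance %s)\n",
              ncol(x$draws), nrow(x$draws),
              paste(sprintf("%.2f", x$acceptance_rate), collapse = ", ")))
  invisible(x)
}

#' Pooled summaries of a chain set
#'
#' @param x A `chain_set`.
#' @param ... Unused.
#' @return `glance()`: a one-row tibble with the pooled posterior mean, sd,
#'   2.5/97.5 percentiles, total retained draws and mean acceptance rate.
#' @method glance chain_set
#' @export
glance.chain_set <- function(x, ...) {
  d <- as.vector(x$draws)
  q <- quantile(d, c(0.025, 0.975), names = FALSE)
  tibble(mean = mean(d), sd = sd(d), lower = q[1], upper = q[2],
         n_draws = length(d), chains = ncol(x$draws),
         acceptance = mean(x$acceptance_rate))
}

#' @rdname tidy.beta_params
#' @method tidy chain_set
#' @export
tidy.chain_set <- function(x, ...) {
  as_tibble(as.data.frame(x$draws)) |>
    setNames(paste0("chain_", seq_len(ncol(x$draws)))) |>
    dplyr::mutate(iteration = dplyr::row_number(), .before = 1) |>
    tidyr::pivot_longer(-"iteration", names_to = "chain", names_prefix = "chain_",
                        values_to = "value") |>
    dplyr::mutate(chain = as.integer(.data$chain)) |>
    dplyr::arrange(.data$chain, .data$iteration)
}

#' Summarise MCMC draws as a prevalence result
#'
#' Pooled posterior mean, sd and equal-tailed percentile interval from the
#' retained draws, with convergence diagnostics attached.
#'
#' @param chains A `chain_set` from [mcmc_sample()].
#' @param level Credible level, default 0.95.
#' @param diagnostics A [convergence_report()] result; computed if `NULL`.
#' @return A `prevalence_result` (method "mcmc") carrying `diagnostics` and
#'   the exact conjugate twin in `closed_form`.
#' @export
mcmc_summary <- function(chains, level = 0.95, diagnostics = NULL) {
  stopifnot(inherits(chains, "chain_set"))
  d <- as.vector(chains$draws)
  tail <- (1 - level) / 2
  q <- quantile(d, c(tail, 1 - tail), names = FALSE)
  if (is.null(diagnostics)) diagnostics <- convergence_report(chains)
  cf <- posterior_summary(chains$posterior, level)
  new_prevalence_result("mcmc", mean(d), q[1], q[2], sd(d), "CrI", level,
                        extra = list(diagnostics = diagnostics,
                                     closed_form = cf,
                                     discrepancy = mean(d) - cf$estimate))
}

#' Export retained draws as CSV (one column per chain)
#'
#' @param chains A `chain_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(chains, path) {
  stopifnot(inherits(chains, "chain_set"))
  df <- as.data.frame(chains$draws)
  names(df) <- paste0("chain_", seq_len(ncol(chains$draws)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
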
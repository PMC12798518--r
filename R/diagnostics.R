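# Convergence diagnostics: rank-normalized split R-hat and bulk/tail
# effective sample size, with Geyer initial-monotone-sequence truncation
# of the autocorrelation sum.

# Split each chain (column) in half -> 2M half-chains of length floor(N/2).
split_chains <- function(draws) {
  n <- nrow(draws)
  half <- n %/% 2L
  lower <- draws[seq_len(half), , drop = FALSE]
  upper <- draws[seq.int(n - half + 1L, n), , drop = FALSE]
  cbind(lower, upper)
}

# Rank-normalize pooled draws: ranks (average ties) -> normal scores via
# the inverse normal CDF of (r - 3/8) / (S + 1/4).
z_scale <- function(draws) {
  r <- rank(as.vector(draws), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow = nrow(draws), ncol = ncol(draws))
}

# Classic potential-scale-reduction on already-prepared half-chains.
rhat_basic <- function(m) {
  n <- nrow(m)
  within <- apply(m, 2, var)
  w <- mean(within)
  if (!is.finite(w) || w <= .Machine$double.eps) return(NA_real_)
  b <- n * var(colMeans(m))
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Rank-normalized split R-hat
#'
#' Each chain is split in half; all draws are rank-normalized jointly
#' (ranks to normal scores); R-hat compares the between-half-chain variance
#' of means to the mean within-half-chain variance:
#' `sqrt(((N-1)/N * W + B/N) / W)` with `B = N * var(half-chain means)`.
#' Values near 1 indicate the chains have mixed; constant chains yield
#' `NA` (reported and treated as a convergence failure).
#'
#' @param chains A `chain_set` from [mcmc_sample()], or a numeric matrix of
#'   draws with one column per chain.
#' @return A single number (or `NA` for degenerate chains).
#' @export
split_rhat <- function(chains) {
  draws <- chain_draws(chains)
  if (nrow(draws) < 4L) {
    abort("At least 4 retained draws per chain are required for split R-hat.",
          class = "prevbayes_diagnostics_error")
  }
  rhat_basic(z_scale(split_chains(draws)))
}

chain_draws <- function(chains) {
  if (inherits(chains, "chain_set")) return(chains$draws)
  if (is.numeric(chains) && is.matrix(chains)) return(chains)
  if (is.numeric(chains)) return(matrix(chains, ncol = 1L))
  abort("`chains` must be a chain_set or a draws matrix.",
        class = "prevbayes_diagnostics_error")
}

#' Autocorrelation of a single chain
#'
#' Autocorrelations by lag under the standard biased (1/N) autocovariance
#' normalization, so `acf[1]` (lag 0) is always exactly 1.
#'
#' @param chain Numeric vector of draws from one chain.
#' @param max_lag Largest lag to compute; must be less than the chain length.
#' @return Numeric vector of length `max_lag + 1` (lags 0..max_lag).
#' @export
autocorr <- function(chain, max_lag) {
  chain <- as.numeric(chain)
  n <- length(chain)
  max_lag <- check_count(max_lag, "max_lag", positive = FALSE)
  if (max_lag >= n) {
    abort("`max_lag` must be smaller than the chain length.",
          class = "prevbayes_diagnostics_error")
  }
  rho <- as.vector(acf(chain, lag.max = max_lag, plot = FALSE,
                       demean = TRUE, type = "correlation")$acf)
  rho[1] <- 1  # exact by definition; acf() carries float round-off
  rho
}

# Combined multi-chain integrated autocorrelation time on prepared
# half-chains, with Geyer initial-positive + monotone truncation.
# Returns ESS = M*N / tau, capped at M*N.
ess_basic <- function(m) {
  n <- nrow(m)
  n_chains <- ncol(m)
  if (n < 4L) return(NA_real_)
  within <- apply(m, 2, var)
  w <- mean(within)
  if (!is.finite(w) || w <= .Machine$double.eps) return(NA_real_)
  b <- if (n_chains > 1L) n * var(colMeans(m)) else 0
  var_plus <- (n - 1) / n * w + b / n

  # per-chain autocorrelations (biased normalization), combined across
  # chains via within/between variances
  acfs <- vapply(seq_len(n_chains), function(j) {
    if (within[j] <= .Machine$double.eps) return(numeric(n))  # constant chain
    autocorr(m[, j], n - 1L)
  }, numeric(n))
  acfs[!is.finite(acfs)] <- 0
  rho <- 1 - (w - colMeans(t(acfs) * within)) / var_plus
  # colMeans above: mean_j within_j * rho_{t,j}; acfs is (n x chains)
  rho[1] <- 1

  # Geyer: sum lag pairs, truncate before the first negative pair, then
  # enforce a monotone non-increasing sequence.
  max_pairs <- (n - 1L) %/% 2L
  tau <- 0
  prev <- Inf
  for (kk in seq_len(max_pairs + 1L) - 1L) {
    i1 <- 2L * kk + 1L
    i2 <- 2L * kk + 2L
    if (i2 > n) break
    g <- rho[i1] + rho[i2]
    if (!is.finite(g) || (kk > 0L && g < 0)) break
    g <- min(g, prev)
    if (g < 0) g <- 0
    tau <- tau + g
    prev <- g
  }
  tau <- 2 * tau - 1
  tau <- max(tau, 1 / log10(n * n_chains + 10))
  min(n * n_chains / tau, n * n_chains)
}

#' Bulk effective sample size
#'
#' Effective number of independent draws for central-tendency estimates:
#' the chains are split in half, rank-normalized, and the multi-chain
#' autocorrelation sum is truncated with Geyer's initial monotone positive
#' sequence. Capped at the total number of retained draws.
#'
#' @inheritParams split_rhat
#' @return A single number (or `NA` for degenerate chains).
#' @export
ess_bulk <- function(chains) {
  draws <- chain_draws(chains)
  if (nrow(draws) < 4L) {
    abort("At least 4 retained draws per chain are required for ESS.",
          class = "prevbayes_diagnostics_error")
  }
  ess_basic(z_scale(split_chains(draws)))
}

#' Tail effective sample size
#'
#' Minimum of the effective sample sizes of the indicator variables
#' `I(draw <= q0.05)` and `I(draw <= q0.95)` (quantiles of the pooled
#' draws), each rank-normalized before the autocorrelation computation.
#' Measures reliability of tail-quantile estimates.
#'
#' @inheritParams split_rhat
#' @return A single number (or `NA` for degenerate chains).
#' @export
ess_tail <- function(chains) {
  draws <- chain_draws(chains)
  if (nrow(draws) < 4L) {
    abort("At least 4 retained draws per chain are required for ESS.",
          class = "prevbayes_diagnostics_error")
  }
  qs <- quantile(as.vector(draws), c(0.05, 0.95), names = FALSE)
  ess_q <- vapply(qs, function(q) {
    ind <- matrix(as.numeric(draws <= q), nrow = nrow(draws))
    ess_basic(z_scale(split_chains(ind)))
  }, numeric(1))
  if (any(is.na(ess_q))) return(NA_real_)
  min(ess_q)
}

#' Convergence report for a chain set
#'
#' Computes rank-normalized split R-hat, bulk and tail effective sample
#' sizes and per-chain autocorrelations, applies the pass thresholds, and
#' bundles gridded trace and density summaries for plotting. The chains
#' are declared converged only if R-hat is defined and at most
#' `rhat_threshold` AND both effective sample sizes reach `ess_floor`;
#' every failed check is listed in `reasons`.
#'
#' @inheritParams split_rhat
#' @param rhat_threshold Pass threshold for R-hat (default 1.01).
#' @param ess_floor Minimum bulk and tail ESS (default 1000).
#' @param acf_lags Number of autocorrelation lags to report.
#' @return A `diagnostics_summary` list with fields `rhat`, `ess_bulk`,
#'   `ess_tail`, `acf` (tibble: chain, lag, acf), `converged`, `reasons`,
#'   `trace` (per-chain window means) and `density` (pooled kernel density
#'   grid).
#' @export
convergence_report <- function(chains, rhat_threshold = 1.01,
                               ess_floor = 1000, acf_lags = 20) {
  draws <- chain_draws(chains)
  n <- nrow(draws)
  m <- ncol(draws)
  rhat <- split_rhat(draws)
  essb <- ess_bulk(draws)
  esst <- ess_tail(draws)

  reasons <- character(0)
  if (is.na(rhat)) {
    reasons <- c(reasons, "R-hat undefined (degenerate chains)")
  } else if (rhat > rhat_threshold) {
    reasons <- c(reasons, sprintf("R-hat %.3f > %.2f", rhat, rhat_threshold))
  }
  if (is.na(essb) || essb < ess_floor) {
    reasons <- c(reasons, sprintf("bulk ESS %s < %d",
                                  ifelse(is.na(essb), "undefined", sprintf("%.0f", essb)),
                                  ess_floor))
  }
  if (is.na(esst) || esst < ess_floor) {
    reasons <- c(reasons, sprintf("tail ESS %s < %d",
                                  ifelse(is.na(esst), "undefined", sprintf("%.0f", esst)),
                                  ess_floor))
  }

  lags <- min(acf_lags, n - 1L)
  acf_tbl <- purrr::map_dfr(seq_len(m), function(j) {
    tibble(chain = j, lag = 0:lags, acf = autocorr(draws[, j], lags))
  })

  n_windows <- min(50L, n)
  win <- ceiling(seq_len(n) / (n / n_windows))
  trace_tbl <- purrr::map_dfr(seq_len(m), function(j) {
    tibble(chain = j, window = seq_len(n_windows),
           mean = as.vector(tapply(draws[, j], win, mean)))
  })

  pooled_sd <- sd(as.vector(draws))
  dens <- if (is.finite(pooled_sd) && pooled_sd > 0) {
    d <- density(as.vector(draws), n = 256)
    tibble(x = d$x, density = d$y)
  } else {
    tibble(x = numeric(0), density = numeric(0))
  }

  structure(list(rhat = rhat, ess_bulk = essb, ess_tail = esst,
                 acf = acf_tbl, converged = length(reasons) == 0L,
                 reasons = reasons, rhat_threshold = rhat_threshold,
                 ess_floor = ess_floor, n_retained = n * m,
                 trace = trace_tbl, density = dens),
            class = "diagnostics_summary")
}

#' @export
print.diagnostics_summary <- function(x, ...) {
  cat(sprintf("<diagnostics_summary> R-hat %s | bulk ESS %s | tail ESS %s -> %s\n",
              ifelse(is.na(x$rhat), "NA", sprintf("%.3f", x$rhat)),
              ifelse(is.na(x$ess_bulk), "NA", sprintf("%.0f", x$ess_bulk)),
              ifelse(is.na(x$ess_tail), "NA", sprintf("%.0f", x$ess_tail)),
              if (x$converged) "converged" else "NOT converged"))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.beta_params
#' @method tidy diagnostics_summary
#' @export
tidy.diagnostics_summary <- function(x, ...) {
  tibble(rhat = x$rhat, ess_bulk = x$ess_bulk, ess_tail = x$ess_tail,
         converged = x$converged,
         reasons = paste(x$reasons, collapse = "; "))
}
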
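#' Beta distribution parameters
#'
#' Container for the `(alpha, beta)` shape parameters of a beta distribution
#' on the prevalence scale. The same class serves as prior and as exact
#' conjugate posterior. `label` records provenance (which counts the prior
#' was elicited from, or "non-informative").
#'
#' @param alpha,beta Positive shape parameters (pseudo-successes and
#'   pseudo-failures).
#' @param label Provenance label.
#' @return An object of class `beta_params`.
#' @examples
#' beta_params(633, 430, "cohort A administrative counts")
#' @export
beta_params <- function(alpha, beta, label = "beta") {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0 ||
      !is.numeric(beta) || length(beta) != 1L || is.na(beta) || beta <= 0) {
    abort("`alpha` and `beta` must be single positive numbers.",
          class = "prevbayes_config_error")
  }
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 label = as.character(label)),
            class = "beta_params")
}

#' @export
print.beta_params <- function(x, ...) {
  s <- beta_stats(x)
  cat(sprintf("<beta_params> Beta(%g, %g) [%s]\n  mean %.4f, sd %.4f, 95%% interval (%.4f, %.4f)\n",
              x$alpha, x$beta, x$label, s$mean, s$sd, s$lower, s$upper))
  invisible(x)
}

#' Elicit an informative beta prior from administrative case counts
#'
#' Converts observed counts from an external source into a beta prior via
#' the pseudo-count rule `alpha = k + 1`, `beta = n - k + 1`: each observed
#' case (non-case) contributes one pseudo-success (pseudo-failure) on top of
#' a uniform Beta(1, 1) base. With zero information the rule reduces to the
#' non-informative prior.
#'
#' @param counts A [count_data] object, e.g. administrative cases among the
#'   persons of one cohort.
#' @return A [beta_params] prior labelled with the counts' source.
#' @examples
#' elicit_prior(count_data(1061, 632, "cohort A admin"))
#' @seealso [noninformative_prior()], [conjugate_posterior()]
#' @export
elicit_prior <- function(counts) {
  counts <- as_count_data(counts, "counts")
  beta_params(counts$k + 1, counts$n - counts$k + 1, counts$label)
}

#' Non-informative uniform prior
#'
#' Beta(1, 1): uniform density on (0, 1), assigning equal prior probability
#' to every prevalence value so the data dominate the posterior.
#'
#' @return A [beta_params] object with `alpha = beta = 1`.
#' @export
noninformative_prior <- function() {
  beta_params(1, 1, "non-informative")
}

#' Exact summaries of a beta distribution
#'
#' Mean, standard deviation and equal-tailed interval of a beta
#' distribution, computed in closed form (moments) and via the exact beta
#' quantile function (interval endpoints).
#'
#' @param p A [beta_params] object.
#' @param level Interval probability content, default 0.95 (equal-tailed:
#'   `(1 - level) / 2` cut from each side).
#' @return A one-row tibble with columns `alpha`, `beta`, `mean`, `sd`,
#'   `lower`, `upper`, `level`.
#' @examples
#' beta_stats(beta_params(944, 668))
#' @export
beta_stats <- function(p, level = 0.95) {
  stopifnot(inherits(p, "beta_params"))
  check_prob(level, "level", allow_zero_one = FALSE)
  a <- p$alpha
  b <- p$beta
  m <- a / (a + b)
  s <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  tail <- (1 - level) / 2
  q <- qbeta(c(tail, 1 - tail), a, b)
  if (any(!is.finite(q))) {
    abort("Beta quantile computation failed to produce finite endpoints.",
          class = "prevbayes_numeric_error")
  }
  # qbeta is accurate to near machine precision; guard against silent
  # failure by round-tripping through the CDF.
  if (max(abs(pbeta(q, a, b) - c(tail, 1 - tail))) > 1e-8) {
    abort("Beta quantile did not invert the CDF to tolerance.",
          class = "prevbayes_numeric_error")
  }
  tibble(alpha = a, beta = b, mean = m, sd = s,
         lower = q[1], upper = q[2], level = level)
}

#' Tidy methods for prevbayes objects
#'
#' Broom-style one-row-per-quantity summaries.
#'
#' @param x A prevbayes object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy beta_params
#' @export
tidy.beta_params <- function(x, ...) {
  s <- beta_stats(x)
  tibble(label = x$label, alpha = x$alpha, beta = x$beta,
         mean = s$mean, sd = s$sd, lower = s$lower, upper = s$upper)
}

#' Serialize / deserialize a beta prior as JSON
#'
#' @param p A [beta_params] object.
#' @param path File to write; if `NULL`, returns the JSON string.
#' @return `prior_to_json()`: the JSON string (invisibly if written to a
#'   file); `prior_from_json()`: a [beta_params] object.
#' @export
prior_to_json <- function(p, path = NULL) {
  stopifnot(inherits(p, "beta_params"))
  js <- jsonlite::toJSON(list(label = p$label, alpha = p$alpha, beta = p$beta),
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(as.character(js))
}

#' @rdname prior_to_json
#' @param json A JSON string or path to a JSON file with fields `alpha`,
#'   `beta` and optionally `label`, or counts `n`, `k` to be elicited.
#' @export
prior_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  if (all(c("alpha", "beta") %in% names(x))) {
    return(beta_params(x$alpha, x$beta, x$label %||% "prior"))
  }
  if (all(c("n", "k") %in% names(x))) {
    return(elicit_prior(count_data(x$n, x$k, x$label %||% "counts")))
  }
  abort("Prior JSON must contain either {alpha, beta} or counts {n, k}.",
        class = "prevbayes_config_error")
}
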
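#' Case counts from one ascertainment source
#'
#' A `count_data` object holds the sufficient statistic of the Bernoulli
#' likelihood: the number of persons ascertained (`n`) and the number of
#' cases among them (`k`), together with a source label so downstream
#' reports can cite where the counts came from.
#'
#' @param n Number of persons ascertained (positive integer).
#' @param k Number of cases, `0 <= k <= n`.
#' @param label Free-text provenance label for the source.
#'
#' @return An object of class `count_data` with fields `n`, `k`, `label`.
#' @examples
#' count_data(549, 311, "self-report completers")
#' @export
count_data <- function(n, k, label = "counts") {
  n <- check_count(n, "n", positive = TRUE)
  k <- check_count(k, "k", positive = FALSE)
  if (k < 0 || k > n) {
    abort(sprintf("`k` must satisfy 0 <= k <= n, got k = %d, n = %d.", k, n),
          class = "prevbayes_config_error")
  }
  structure(list(n = n, k = k, label = as.character(label)),
            class = "count_data")
}

#' @export
print.count_data <- function(x, ...) {
  cat(sprintf("<count_data> %s: k = %d cases of n = %d (%.2f%%)\n",
              x$label, x$k, x$n, 100 * x$k / x$n))
  invisible(x)
}

#' @rdname tidy.beta_params
#' @method tidy count_data
#' @export
tidy.count_data <- function(x, ...) {
  tibble(label = x$label, n = x$n, k = x$k, proportion = x$k / x$n)
}

as_count_data <- function(x, arg = "data") {
  if (inherits(x, "count_data")) return(x)
  if (is.list(x) && all(c("n", "k") %in% names(x))) {
    return(count_data(x$n, x$k, x$label %||% "counts"))
  }
  abort(sprintf("`%s` must be a count_data object (see `count_data()`).", arg),
        class = "prevbayes_config_error")
}
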
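# broom-style methods for fitted objects.

#' Tidy a fitted gain/loss model
#'
#' @param x A `uv_gainloss` object (see [fit_gain_loss()]).
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @method tidy uv_gainloss
#' @export
tidy.uv_gainloss <- function(x, ...) {
  tibble(term = c("gain_rate", "loss_rate", "gamma_shape"),
         estimate = c(x$g, x$l, x$alpha))
}

#' One-row summary of a fitted gain/loss model
#'
#' @param x A `uv_gainloss` object.
#' @param ... Unused.
#' @return Tibble with `logLik`, `n_categories`, `root_prior`,
#'   `boundary`, `n_restarts_used` (NA for unfitted models).
#' @method glance uv_gainloss
#' @export
glance.uv_gainloss <- function(x, ...) {
  tibble(logLik = x$logLik %||% NA_real_,
         n_categories = x$n_categories,
         root_prior = if (identical(x$root_prior, "stationary"))
           "stationary" else "fixed",
         boundary = x$boundary %||% NA,
         n_restarts_used = x$n_restarts_used %||% NA_integer_)
}

#' Tidy a demonstration report
#'
#' @param x A `uv_demo_report` from [run_demo()].
#' @param ... Unused.
#' @return Long tibble of the summary metrics (`metric`, `value`).
#' @method tidy uv_demo_report
#' @export
tidy.uv_demo_report <- function(x, ...) {
  x$summary |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric",
                        values_to = "value")
}
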
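#' Tidy and summarise model-evaluation results
#'
#' `tidy()` returns one row per paired data point with its relative error;
#' `glance()` returns the per-variable one-line summary (the CSV layout of
#' the `evaluate` command).
#'
#' @param x a `model_evaluation` from [evaluate_model()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.model_evaluation <- function(x, ...) {
  as_tibble(x) |>
    select("variable", "errors") |>
    tidyr::unnest_longer("errors", values_to = "e_r", indices_to = "point") |>
    select("variable", "point", "e_r")
}

#' @rdname tidy.model_evaluation
#' @export
glance.model_evaluation <- function(x, ...) {
  as_tibble(x) |>
    select("variable", "n", e_bar_pct = "e_bar", sd_pct = "sd")
}

#' Tidy and summarise rate estimates
#'
#' `tidy()` pivots the per-interval estimates to one row per interval and
#' rate; `glance()` gives per-rate medians across intervals, split by
#' regime.
#'
#' @param x a `rate_estimates` from [estimate_rates()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.rate_estimates <- function(x, ...) {
  qcols <- grep("^q_", names(x), value = TRUE)
  as_tibble(x) |>
    tidyr::pivot_longer(all_of(c("mu", qcols)),
                        names_to = "rate", values_to = "estimate") |>
    select("t_start", "t_end", "regime", "rate", "estimate", "reason")
}

#' @rdname tidy.rate_estimates
#' @export
glance.rate_estimates <- function(x, ...) {
  tidy(x) |>
    group_by(.data$regime, .data$rate) |>
    summarise(n = sum(!is.na(.data$estimate)),
              median = median(.data$estimate, na.rm = TRUE),
              .groups = "drop")
}
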
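#' Plot a simulated trajectory
#'
#' Faceted time courses of the simulated state: viable cell density
#' (reported per mL), metabolites, osmolality, mean aggregate diameter and
#' the applied perfusion rate.
#'
#' @param object a `perfusion_trajectory` from [simulate_process()].
#' @param variables which state variables to facet.
#' @param ... unused.
#' @return A ggplot object.
#' @examples
#' autoplot(simulate_reference())
#' @export
autoplot.perfusion_trajectory <- function(object,
                                          variables = c("X", "glc", "lac",
                                                        "gln", "osm", "d_agg"),
                                          ...) {
  long <- trajectory_long(object, variables)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(colour = "#2171b5") +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = "process time [d]", y = NULL,
                  title = "Simulated perfusion process") +
    ggplot2::theme_minimal()
}

trajectory_long <- function(traj, variables) {
  labels <- c(X = "viable cells [1e6/mL]", glc = "glucose [mM]",
              lac = "lactate [mM]", gln = "glutamine [mM]",
              osm = "osmolality [mOsm/kg]", d_agg = "aggregate diameter [um]",
              F = "feed flow [L/d]", mu_eff = "specific growth rate [1/d]")
  df <- as_tibble(traj)
  df$X <- df$X / 1e9   # cells/L -> 1e6 cells/mL
  df |>
    select(all_of(c("t", variables))) |>
    tidyr::pivot_longer(-"t", names_to = "variable") |>
    mutate(label = factor(labels[.data$variable], levels = labels[variables]))
}

#' Plot a trajectory against observed process samples
#'
#' Overlay of the model time courses (lines) and sampled observations
#' (points), one facet per shared variable -- the visual companion of
#' [evaluate_model()].
#'
#' @param traj a `perfusion_trajectory`.
#' @param obs a `process_series` (e.g. from [read_process_csv()] or
#'   [synthesize_process()]).
#' @param variables shared variables to facet.
#' @return A ggplot object.
#' @examples
#' plot_fit(simulate_reference(), synthesize_process(sampling_times = 0:7))
#' @export
plot_fit <- function(traj, obs, variables = c("X", "glc", "lac", "gln")) {
  long_m <- trajectory_long(traj, variables)
  long_o <- trajectory_long(obs, intersect(variables, names(obs)))
  ggplot2::ggplot(long_m, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(colour = "#2171b5") +
    ggplot2::geom_point(data = long_o, colour = "#cb181d", size = 1.6) +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = "process time [d]", y = NULL,
                  title = "Model (line) vs observations (points)") +
    ggplot2::theme_minimal()
}

#' Plot estimated cell-specific rates per interval
#'
#' @param object a `rate_estimates` tibble from [estimate_rates()].
#' @param ... unused.
#' @return A ggplot object of step-style per-interval estimates.
#' @export
autoplot.rate_estimates <- function(object, ...) {
  qcols <- grep("^q_", names(object), value = TRUE)
  long <- as_tibble(object) |>
    select(all_of(c("t_start", "t_end", "mu", qcols))) |>
    tidyr::pivot_longer(-c("t_start", "t_end"), names_to = "rate")
  ggplot2::ggplot(long) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$t_start, xend = .data$t_end,
                                       y = .data$value, yend = .data$value),
                          colour = "#238b45", linewidth = 1) +
    ggplot2::facet_wrap(~rate, scales = "free_y") +
    ggplot2::labs(x = "process time [d]", y = NULL,
                  title = "Per-interval cell-specific rates") +
    ggplot2::theme_minimal()
}
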
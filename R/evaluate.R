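#' Relative prediction errors against wet-lab data
#'
#' Per-point relative error of modelled values against measured ("wet-lab")
#' values, normalised by the single series-wide wet-lab maximum:
#' `e_i = |wl_i - m_i| / max(wl) * 100` (percent). Normalising by the series
#' maximum (not per point) keeps early near-zero measurements from blowing
#' up the error of an otherwise faithful growth curve.
#'
#' @param wl numeric vector of measured values.
#' @param m numeric vector of modelled values, same length.
#' @return Vector of per-point errors (%).
#' @examples
#' relative_errors(c(10, 20), c(12, 16))   # 10, 20
#' @export
relative_errors <- function(wl, m) {
  if (length(wl) != length(m) || length(wl) < 1)
    abort("series must have equal length >= 1", class = "perfusim_domain_error")
  if (anyNA(wl) || anyNA(m))
    abort("series must not contain NA", class = "perfusim_domain_error")
  if (max(wl) <= 0)
    abort("wet-lab series maximum must be > 0 to normalise",
          class = "perfusim_normalization_error")
  abs(wl - m) / max(wl) * 100
}

#' Mean and spread of a relative-error vector
#'
#' `mean_error()` is the arithmetic mean of the per-point errors;
#' `sd_error()` is their sample standard deviation (n - 1 denominator,
#' defined for n >= 2). Both are in percent, like their input.
#'
#' @param e numeric vector of per-point errors (%), from [relative_errors()].
#' @return A percentage.
#' @examples
#' mean_error(c(10, 20))   # 15
#' sd_error(c(10, 20))     # sqrt(50)
#' @export
mean_error <- function(e) {
  if (length(e) < 1) abort("empty error vector", class = "perfusim_domain_error")
  mean(e)
}

#' @rdname mean_error
#' @export
sd_error <- function(e) {
  if (length(e) < 2)
    abort("sd_error needs at least two points", class = "perfusim_domain_error")
  sd(e)
}

#' Evaluate a simulated trajectory against observed process data
#'
#' Pairs each observation with the nearest trajectory point within `t_tol`
#' and computes the relative prediction-error summary per requested
#' variable. Unpaired observations are reported in the `n_unpaired` column
#' (and kept in the `unpaired` attribute), never silently dropped.
#'
#' @param traj a `perfusion_trajectory` from [simulate_process()] (or any
#'   data frame with column `t` plus the requested variables).
#' @param obs observed samples: a data frame with column `t` plus the
#'   requested variables (cells/L for `X`, as returned by
#'   [read_process_csv()]).
#' @param variables character vector of shared column names to compare.
#' @param t_tol maximum |t_obs - t_model| for a pairing (day).
#' @return A `model_evaluation` tibble with one row per variable: `variable`,
#'   `n`, `e_bar` (mean error, %), `sd` (%, NA for n < 2), `n_unpaired`, and
#'   an `errors` list-column of the per-point errors.
#' @examples
#' traj <- simulate_reference()
#' obs <- synthesize_process(sampling_times = 0:7)
#' evaluate_model(traj, obs, variables = c("X", "glc", "lac"))
#' @export
evaluate_model <- function(traj, obs, variables = c("X", "glc", "lac", "gln"),
                           t_tol = 0.02) {
  traj <- as_tibble(traj); obs <- as_tibble(obs)
  stopifnot(all(c("t", variables) %in% names(traj)),
            all(c("t", variables) %in% names(obs)))
  idx <- map_dbl(obs$t, function(tt) {
    j <- which.min(abs(traj$t - tt))
    if (abs(traj$t[j] - tt) <= t_tol) j else NA_real_
  })
  paired <- !is.na(idx)
  if (!any(paired))
    abort("no observation pairs with the trajectory within t_tol",
          class = "perfusim_pairing_error")
  rows <- map(variables, function(v) {
    wl <- obs[[v]][paired]
    m <- traj[[v]][idx[paired]]
    keep <- !is.na(wl) & !is.na(m)
    e <- relative_errors(wl[keep], m[keep])
    tibble(variable = v, n = length(e),
           e_bar = mean_error(e),
           sd = if (length(e) >= 2) sd_error(e) else NA_real_,
           n_unpaired = sum(!paired) + sum(!keep),
           errors = list(e))
  })
  out <- bind_rows(rows)
  structure(out, class = c("model_evaluation", class(tibble())),
            unpaired = obs[!paired, , drop = FALSE], t_tol = t_tol)
}
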
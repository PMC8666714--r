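#' Instantaneous process state
#'
#' A one-row tibble holding the simulator state: time, viable cell density,
#' metabolite concentrations, osmolality, mean aggregate diameter and working
#' volume. Cell density is carried internally in cells/L so that
#' `q * X` yields mM/day without conversion factors.
#'
#' @param t process time (day).
#' @param X viable cell density (cells/L).
#' @param glc,lac,gln glucose, lactate, glutamine (mM).
#' @param osm osmolality (mOsm/kg).
#' @param d_agg mean aggregate diameter (um); use the single-cell diameter
#'   before aggregation onset.
#' @param V working volume (L); constant under perfusion (equal feed and
#'   waste flow with full cell retention).
#' @return A one-row tibble of class `process_state`.
#' @examples
#' process_state(X = 0.5e9, glc = 17.5, gln = 2.5, V = 0.15)
#' @export
process_state <- function(t = 0, X, glc, lac = 0, gln, osm = 317.5,
                          d_agg = 15, V) {
  vals <- c(t = t, X = X, glc = glc, lac = lac, gln = gln, osm = osm,
            d_agg = d_agg, V = V)
  if (any(!is.finite(vals)))
    abort("all state components must be finite", class = "perfusim_invalid_parameter")
  if (X < 0 || glc < 0 || lac < 0 || gln < 0 || d_agg < 0)
    abort("cell density, concentrations and aggregate diameter must be >= 0",
          class = "perfusim_invalid_parameter")
  if (V <= 0) abort("working volume must be > 0", class = "perfusim_invalid_parameter")
  out <- tibble(t = t, X = X, glc = glc, lac = lac, gln = gln,
                osm = osm, d_agg = d_agg, V = V)
  class(out) <- c("process_state", class(out))
  out
}

# Mass-balance right-hand side at piecewise-constant perfusion.
# y: named vector (X, glc, lac, gln, osm, d_agg); F in L/day; feed may be NULL
# (batch). Concentrations are clamped at zero inside the Monod factors, which
# also suppresses turnover of an exhausted species (mu -> 0).
# Metabolite turnover is growth-associated: the effective per-cell rates are
# the maximal rates scaled by mu/mu_max, so consumption and production track
# the cells' actual proliferative activity and fall to zero as growth stalls.
process_rhs <- function(t, y, p, F_rate, feed, V) {
  glc <- max(y[["glc"]], 0); gln <- max(y[["gln"]], 0)
  lac <- max(y[["lac"]], 0); osm <- y[["osm"]]
  d_agg <- max(y[["d_agg"]], 0); X <- max(y[["X"]], 0)

  f_glc <- glc / (p$K_Glc + glc)
  f_gln <- gln / (p$K_Gln + gln)
  mu <- p$mu_max * f_glc * f_gln *
    p$K_Lac / (p$K_Lac + lac) *
    p$K_Osm / (p$K_Osm + max(0, osm - p$osm_ref)) *
    p$K_Agg / (p$K_Agg + d_agg / 2)
  g <- mu / p$mu_max                    # growth-association factor in [0, 1]

  D <- F_rate / V                       # dilution rate, 1/day
  glc_f <- if (is.null(feed)) glc else feed$glc
  gln_f <- if (is.null(feed)) gln else feed$gln
  lac_f <- if (is.null(feed)) lac else feed$lac
  osm_f <- if (is.null(feed)) osm else feed$osm

  list(c(
    X     = mu * X,
    glc   = -p$q_Glc_max * g * X + D * (glc_f - glc),
    lac   =  p$q_Lac_max * g * X + D * (lac_f - lac),
    gln   = -p$q_Gln_max * g * X + D * (gln_f - gln),
    osm   =  p$k_osm * p$q_Lac_max * g * X + D * (osm_f - osm),
    d_agg = if (t >= p$t_agg) (mu / 3) * d_agg else 0
  ))
}

#' Simulate a perfused expansion process
#'
#' Integrates the Monod-kinetic mass balances over a perfusion feed schedule.
#' The perfusion rate and feed composition are piecewise constant; the
#' integrator is restarted at every schedule boundary and at the aggregation
#' onset time, so feed switches are exact events rather than smoothed
#' transitions. At `t_agg` the mean aggregate diameter is reset to
#' `d_agg_init` (aggregate nucleation), after which it follows the cube-root
#' growth law `d' = mu * d / 3`, i.e. diameter tracks `X^(1/3)`.
#'
#' Working volume is constant (perfusion exchanges equal feed and waste
#' volumes with cells fully retained). No death term is carried: the model
#' describes the viable density of a high-viability process.
#'
#' @param initial a [process_state()] (or one-row data frame with the same
#'   columns).
#' @param p a [kinetic_parameters()] object.
#' @param schedule a [feed_schedule()] covering `[initial$t, t_end]`.
#' @param t_end end of integration (day).
#' @param dt_out output grid spacing (day); both endpoints are included.
#' @param atol,rtol absolute and relative integrator tolerances.
#' @return A `perfusion_trajectory`: a tibble with columns `t`, `X`, `glc`,
#'   `lac`, `gln`, `osm`, `d_agg`, `V`, `F` (the active feed flow, L/day) and
#'   `mu_eff` (instantaneous specific growth rate, 1/day), with the
#'   parameters and schedule attached as attributes.
#' @examples
#' traj <- simulate_process(
#'   process_state(X = 0.5e9, glc = 17.5, gln = 2.5, V = 0.15),
#'   kinetic_parameters(), load_builtin("table3_schedule"), t_end = 7)
#' dplyr::last(traj$X) / 1e9   # 1e9 cells/L == 1e6 cells/mL
#' @export
simulate_process <- function(initial, p, schedule, t_end,
                             dt_out = 0.05, atol = 1e-6, rtol = 1e-8) {
  stopifnot(inherits(p, "kinetic_parameters"), inherits(schedule, "feed_schedule"))
  initial <- as_tibble(initial)
  need <- c("t", "X", "glc", "lac", "gln", "osm", "d_agg", "V")
  if (!all(need %in% names(initial)) || nrow(initial) != 1L)
    abort("initial must be a one-row process_state", class = "perfusim_invalid_parameter")
  t0 <- initial$t
  if (t_end <= t0) abort("t_end must exceed initial$t", class = "perfusim_invalid_parameter")
  if (schedule$start_day[1] > t0 || schedule$end_day[nrow(schedule)] < t_end - 1e-9)
    abort("feed schedule must cover the whole integration span",
          class = "perfusim_invalid_parameter")
  V <- initial$V

  grid <- seq(t0, t_end, by = dt_out)
  if (tail(grid, 1) < t_end - 1e-12) grid <- c(grid, t_end)
  # integration is split at schedule boundaries and aggregation onset
  breaks <- sort(unique(c(t0, t_end,
                          schedule$start_day, schedule$end_day, p$t_agg)))
  breaks <- breaks[breaks >= t0 & breaks <= t_end]

  y <- c(X = initial$X, glc = initial$glc, lac = initial$lac,
         gln = initial$gln, osm = initial$osm, d_agg = initial$d_agg)
  pieces <- vector("list", length(breaks) - 1L)
  for (k in seq_len(length(breaks) - 1L)) {
    a <- breaks[k]; b <- breaks[k + 1L]
    if (abs(a - p$t_agg) <= 1e-12) y[["d_agg"]] <- p$d_agg_init
    seg <- schedule_at(schedule, a)
    times <- sort(unique(c(a, grid[grid > a + 1e-12 & grid < b - 1e-12], b)))
    sol <- deSolve::lsoda(
      y = y, times = times, parms = NULL,
      func = function(t, y, parms) process_rhs(t, y, p, seg$rate * V, seg$medium, V),
      atol = atol, rtol = rtol
    )
    if (attr(sol, "istate")[1] < 0 || any(!is.finite(sol)))
      abort(sprintf("integration failed in segment [%g, %g] at state X=%.4g glc=%.4g",
                    a, b, y[["X"]], y[["glc"]]),
            class = "perfusim_integration_error")
    sol <- as.data.frame(sol)
    y <- unlist(sol[nrow(sol), -1])
    sol$F <- seg$rate * V
    pieces[[k]] <- sol
  }
  out <- bind_rows(pieces)
  # at interior breaks keep the incoming segment's row (its F, post-event state)
  out <- out[!duplicated(round(out$time / 1e-9), fromLast = TRUE), , drop = FALSE]
  out <- out[vapply(out$time, function(tt) any(abs(tt - grid) <= 1e-9),
                    logical(1)), , drop = FALSE]

  conc <- c("glc", "lac", "gln")
  if (any(unlist(out[conc]) < -1e-6) || any(out$X < -1e-6))
    abort("negative state beyond clamp tolerance; integration inconsistent",
          class = "perfusim_integration_error")
  for (v in conc) out[[v]] <- pmax(out[[v]], 0)
  out$X <- pmax(out$X, 0)

  traj <- tibble(
    t = out$time, X = out$X, glc = out$glc, lac = out$lac, gln = out$gln,
    osm = out$osm, d_agg = out$d_agg, V = V, F = out$F
  )
  traj$mu_eff <- map_dbl(seq_len(nrow(traj)), function(i)
    specific_growth_rate(traj[i, ], p))
  structure(traj,
            class = c("perfusion_trajectory", class(tibble())),
            parameters = p, schedule = schedule)
}

#' @export
print.perfusion_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<perfusion_trajectory> %d points, t in [%g, %g] d\n",
              n, x$t[1], x$t[n]))
  cat(sprintf("  X: %.3g -> %.3g cells/L (%.1f-fold); day-end d_agg %.0f um\n",
              x$X[1], x$X[n], x$X[n] / x$X[1], x$d_agg[n]))
  NextMethod()
}

#' Reference process simulation
#'
#' Convenience wrapper running the shipped default 7-day reference process:
#' default kinetic parameters, the built-in perfusion schedule, inoculation
#' at 0.5e6 cells/mL in 150 mL of E8 suspension medium.
#'
#' @param t_end end of integration (day).
#' @param dt_out output grid spacing (day).
#' @return A `perfusion_trajectory` (see [simulate_process()]).
#' @export
simulate_reference <- function(t_end = 7, dt_out = 0.05) {
  media <- load_builtin("media_e8")
  p <- kinetic_parameters()
  init <- process_state(t = 0, X = 0.5e9,
                        glc = media$basis$glc, gln = media$basis$gln,
                        lac = 0, osm = media$basis$osm,
                        d_agg = p$d_cell, V = 0.15)
  simulate_process(init, p, load_builtin("table3_schedule"),
                   t_end = t_end, dt_out = dt_out)
}
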
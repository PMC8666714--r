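#' Impeller-speed scale-up at constant power per volume
#'
#' Translates a stirring speed from one stirred-tank configuration to
#' another holding specific power input `N^3 D^5 / V` constant:
#' `N_o = (N_i^3 * (V_o/V_i) * D_i^5/D_o^5)^(1/3)`. Valid only between
#' impellers of the same geometry with an essentially constant
#' impeller-to-vessel diameter ratio.
#'
#' @param N_i known speed (rpm).
#' @param V_i,V_o liquid volumes (L) of the known and target configuration.
#' @param D_i,D_o impeller diameters (m).
#' @return Target speed (rpm).
#' @examples
#' scale_speed(80, V_i = 0.15, D_i = 0.034, V_o = 0.5, D_o = 0.053)
#' @export
scale_speed <- function(N_i, V_i, D_i, V_o, D_o) {
  vals <- c(N_i = N_i, V_i = V_i, D_i = D_i, V_o = V_o, D_o = D_o)
  if (any(!is.finite(vals)) || any(vals <= 0))
    abort("all scale-up inputs must be finite and > 0",
          class = "perfusim_domain_error")
  (N_i^3 * (V_o / V_i) * D_i^5 / D_o^5)^(1 / 3)
}

#' Fitted volume-to-speed laws for the built-in systems
#'
#' Cube-root laws relating working volume to stirring speed,
#' `N = c * V^(1/3)` with V in liters and N in rpm: constant 150.5 for the
#' DASbox (so 0.15 L gives 79.97 ~ the 80 rpm setpoint) and 76.5 for the
#' DASGIP Bioblock. A warning is raised outside the system's working-volume
#' range.
#'
#' @param V working volume (L).
#' @return Stirring speed (rpm).
#' @examples
#' speed_dasbox(0.15)    # 79.97 -> set 80 rpm
#' speed_bioblock(0.5)
#' @export
speed_dasbox <- function(V) cube_root_speed(V, load_builtin("dasbox"))

#' @rdname speed_dasbox
#' @export
speed_bioblock <- function(V) cube_root_speed(V, load_builtin("bioblock"))

cube_root_speed <- function(V, g) {
  if (!is.numeric(V) || any(!is.finite(V)) || any(V <= 0))
    abort("volume must be finite and > 0", class = "perfusim_domain_error")
  outside <- V < g$volume_range[1] | V > g$volume_range[2]
  if (any(outside))
    warn(sprintf("volume outside the %s working range [%g, %g] L",
                 g$name, g$volume_range[1], g$volume_range[2]))
  g$speed_constant * V^(1 / 3)
}

#' Operating stirring-speed bounds at a working volume
#'
#' Scales a system's reference-volume operating window (e.g. 50-120 rpm at
#' 150 mL for the DASbox; below the lower bound aggregates fuse and grow
#' uncontrolled, above the upper bound shear reduces viability) to another
#' volume by the same cube-root volume law as the fitted speed equations.
#'
#' @param V working volume (L).
#' @param g a [reactor_geometry()] carrying reference bounds.
#' @return Named numeric `c(min, max)` (rpm).
#' @examples
#' speed_bounds(0.15, load_builtin("dasbox"))   # 50, 120
#' @export
speed_bounds <- function(V, g) {
  stopifnot(inherits(g, "reactor_geometry"))
  if (!is.finite(g$min_speed_at_ref) || !is.finite(g$max_speed_at_ref) ||
      !is.finite(g$reference_volume))
    abort(sprintf("no reference operating bounds recorded for %s", g$name),
          class = "perfusim_capability_error")
  if (!is.numeric(V) || V <= 0)
    abort("volume must be > 0", class = "perfusim_domain_error")
  s <- (V / g$reference_volume)^(1 / 3)
  c(min = g$min_speed_at_ref * s, max = g$max_speed_at_ref * s)
}

#' Headspace gassing rate rule
#'
#' Gas flow scaled to the vessel: six reactor volumes per hour, i.e.
#' `6 * V` sL/h (0.9 sL/h at the 150 mL reference scale).
#'
#' @param V working volume (L).
#' @return Gassing rate (sL/h).
#' @examples
#' gassing_rate(0.15)   # 0.9
#' @export
gassing_rate <- function(V) {
  if (!is.numeric(V) || any(!is.finite(V)) || any(V <= 0))
    abort("volume must be finite and > 0", class = "perfusim_domain_error")
  6 * V
}

#' Inoculum cell number for a target seeding density
#'
#' @param V working volume (L).
#' @param density target seeding density (cells/mL).
#' @return Required cell number (`V * 1000 * density`); 75e6 cells for
#'   0.5e6 cells/mL at 150 mL.
#' @examples
#' inoculum_cells(0.15, 0.5e6)
#' @export
inoculum_cells <- function(V, density) {
  if (!is.numeric(V) || V <= 0 || !is.numeric(density) || density < 0)
    abort("volume must be > 0 and density >= 0", class = "perfusim_domain_error")
  V * 1000 * density
}

#' Feed-medium volume required over a day span
#'
#' Working volume times the summed working-volumes-per-day rates over the
#' span (partial-day overlaps pro-rated), the bench rule for pre-filling
#' feed bottles. With the reference schedule at 0.15 L this gives 0.825 L of
#' feed medium I for days 1-4 and 2.55 L of feed medium II for days 4-7.
#'
#' @param schedule a [feed_schedule()].
#' @param V working volume (L).
#' @param from_day,to_day span (days), within the schedule.
#' @return Feed volume (L).
#' @examples
#' feed_volume(load_builtin("table3_schedule"), V = 0.15, 1, 4)
#' @export
feed_volume <- function(schedule, V, from_day, to_day) {
  stopifnot(inherits(schedule, "feed_schedule"))
  if (to_day < from_day)
    abort("to_day must be >= from_day", class = "perfusim_ordering_error")
  if (from_day < schedule$start_day[1] - 1e-12 ||
      to_day > schedule$end_day[nrow(schedule)] + 1e-12)
    abort("span must lie within the schedule", class = "perfusim_domain_error")
  overlap <- pmax(0, pmin(schedule$end_day, to_day) -
                     pmax(schedule$start_day, from_day))
  V * sum(schedule$rate * overlap)
}

#' Process planning summary
#'
#' Collects the bench-planning quantities for a run at a given scale:
#' inoculum cell number, stirring speed (when the system has a fitted law),
#' operating speed bounds, gassing rate and per-segment feed volumes.
#'
#' @param V working volume (L).
#' @param density target seeding density (cells/mL).
#' @param schedule a [feed_schedule()].
#' @param g a [reactor_geometry()].
#' @return A list with `summary` (one-row tibble) and `feed` (per-segment
#'   tibble with medium labels and required volumes in L).
#' @examples
#' plan_process(V = 0.15)
#' @export
plan_process <- function(V, density = 0.5e6,
                         schedule = load_builtin("table3_schedule"),
                         g = load_builtin("dasbox")) {
  speed <- if (is.finite(g$speed_constant)) cube_root_speed(V, g) else NA_real_
  bounds <- tryCatch(speed_bounds(V, g),
                     perfusim_capability_error = function(e) c(min = NA_real_, max = NA_real_))
  feed <- tibble(
    start_day = schedule$start_day, end_day = schedule$end_day,
    rate = schedule$rate,
    medium = map(schedule$medium, "label") |> unlist(),
    volume_L = map_dbl(seq_len(nrow(schedule)),
                       ~ feed_volume(schedule, V, schedule$start_day[.x],
                                     schedule$end_day[.x]))
  )
  list(
    summary = tibble(
      volume_L = V, inoculum_cells = inoculum_cells(V, density),
      speed_rpm = speed, speed_min_rpm = bounds[["min"]],
      speed_max_rpm = bounds[["max"]], gassing_sL_h = gassing_rate(V)
    ),
    feed = feed
  )
}
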
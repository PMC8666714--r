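#' Kinetic model parameters
#'
#' Bundles the Monod(-like) constants, maximal cell-specific rates and the
#' aggregate/osmolality model coefficients that drive [simulate_process()].
#' The defaults are the exemplary literature constants for hPSC aggregate
#' expansion together with auxiliary coefficients fixed once by the shipped
#' grid calibration against the reference 7-day process endpoint (see
#' [calibrate_defaults()]; the calibration log is in
#' `system.file("extdata", "calibration-log.csv", package = "perfusim")`).
#'
#' @param K_Glc,K_Lac,K_Gln Monod constants for glucose, lactate and
#'   glutamine (mM). Glucose and glutamine act as limiting substrates
#'   (`c/(K+c)`); lactate acts as an inhibitor (`K/(K+c)`).
#' @param K_Agg critical aggregate *radius* (um); inhibition `K/(K+r)` with
#'   `r = d_agg/2`. The conventional critical diameter of 350 um corresponds
#'   to the default radius of 175 um.
#' @param K_Osm inhibition constant on osmolality excess above `osm_ref`
#'   (mOsm/kg).
#' @param mu_max maximal specific growth rate (1/day).
#' @param q_Glc_max,q_Lac_max,q_Gln_max maximal cell-specific glucose
#'   consumption, lactate production and glutamine consumption
#'   (mmol cell^-1 day^-1).
#' @param agg_f,agg_g dimensionless aggregate formation fraction and
#'   nucleation coefficient (cell-line dependent; used by the optional
#'   nucleation-based initial-diameter rule, see [aggregate_onset_diameter()]).
#' @param k_osm osmolality yield per mM lactate produced (mOsm/kg per mM);
#'   lumps lactate itself with the pH-stabilising bicarbonate addition it
#'   triggers.
#' @param osm_ref reference osmolality (mOsm/kg) below which no osmotic
#'   inhibition applies.
#' @param d_agg_init mean aggregate diameter at aggregation onset (um).
#' @param t_agg aggregation onset time (day).
#' @param d_cell single-cell diameter (um).
#' @param packing volume packing fraction of cells in an aggregate
#'   (dimensionless, in (0, 1]).
#'
#' @return An object of class `kinetic_parameters` (a named list).
#' @examples
#' p <- kinetic_parameters()
#' p$mu_max
#' @export
kinetic_parameters <- function(K_Glc = 1.5,
                               K_Lac = 50,
                               K_Gln = 0.01,
                               K_Agg = 350 / 2,
                               K_Osm = 500,
                               mu_max = 1.35,
                               q_Glc_max = 1.474e-8,
                               q_Lac_max = 2.37e-8,
                               q_Gln_max = 1.856e-9,
                               agg_f = 0.95,
                               agg_g = 0.25,
                               k_osm = 2,
                               osm_ref = 325,
                               d_agg_init = 78,
                               t_agg = 1,
                               d_cell = 15,
                               packing = 0.74) {
  p <- list(
    K_Glc = K_Glc, K_Lac = K_Lac, K_Gln = K_Gln, K_Agg = K_Agg,
    K_Osm = K_Osm, mu_max = mu_max,
    q_Glc_max = q_Glc_max, q_Lac_max = q_Lac_max, q_Gln_max = q_Gln_max,
    agg_f = agg_f, agg_g = agg_g,
    k_osm = k_osm, osm_ref = osm_ref, d_agg_init = d_agg_init,
    t_agg = t_agg, d_cell = d_cell, packing = packing
  )
  validate_kinetic_parameters(p)
  structure(p, class = "kinetic_parameters")
}

validate_kinetic_parameters <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) {
      abort(sprintf("kinetic parameter `%s` must be a single finite number", nm),
            class = "perfusim_invalid_parameter")
    }
  }
  bad <- function(msg) abort(msg, class = "perfusim_invalid_parameter")
  if (any(unlist(p[c("K_Glc", "K_Lac", "K_Gln", "K_Agg", "K_Osm")]) <= 0))
    bad("all Monod constants K_* must be > 0")
  if (p$mu_max <= 0) bad("mu_max must be > 0")
  if (any(unlist(p[c("q_Glc_max", "q_Lac_max", "q_Gln_max")]) < 0))
    bad("maximal specific rates q_*_max must be >= 0")
  if (p$agg_f <= 0 || p$agg_f > 1) bad("agg_f must be in (0, 1]")
  if (p$agg_g <= 0 || p$agg_g > 1) bad("agg_g must be in (0, 1]")
  if (p$k_osm < 0) bad("k_osm must be >= 0")
  if (p$packing <= 0 || p$packing > 1) bad("packing must be in (0, 1]")
  if (p$d_cell <= 0) bad("d_cell must be > 0")
  if (p$d_agg_init < p$d_cell) bad("d_agg_init must be >= d_cell")
  if (p$t_agg < 0) bad("t_agg must be >= 0")
  if (p$osm_ref <= 0) bad("osm_ref must be > 0")
  invisible(p)
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("<kinetic_parameters>\n")
  cat(sprintf("  Monod constants : K_Glc=%g K_Gln=%g K_Lac=%g K_Agg=%g K_Osm=%g\n",
              x$K_Glc, x$K_Gln, x$K_Lac, x$K_Agg, x$K_Osm))
  cat(sprintf("  max rates       : mu=%g /d  q_Glc=%.3g  q_Lac=%.3g  q_Gln=%.3g mmol/cell/d\n",
              x$mu_max, x$q_Glc_max, x$q_Lac_max, x$q_Gln_max))
  cat(sprintf("  aggregates      : agg_f=%g agg_g=%g d_init=%g um at t=%g d (d_cell=%g, packing=%g)\n",
              x$agg_f, x$agg_g, x$d_agg_init, x$t_agg, x$d_cell, x$packing))
  cat(sprintf("  osmolality      : k_osm=%g mOsm/kg per mM, osm_ref=%g mOsm/kg\n",
              x$k_osm, x$osm_ref))
  invisible(x)
}

#' Medium composition
#'
#' Describes a culture or feed medium by the concentrations the kinetic model
#' tracks. Built-in recipes are available via [load_builtin()] (`"media_e8"`):
#' the E8 suspension basis and the two glucose/glutamine-enriched full feed
#' media used on days 1-4 and 4-7 of the reference perfusion schedule.
#'
#' @param glc,gln,lac glucose, glutamine, lactate (mM). Fresh media carry
#'   no lactate.
#' @param osm osmolality (mOsm/kg).
#' @param label identifier used in printing and provenance records.
#' @return An object of class `medium_composition` (a named list).
#' @examples
#' medium_composition(glc = 34.15, gln = 4.5, osm = 337.5, label = "feed I")
#' @export
medium_composition <- function(glc, gln, lac = 0, osm, label = "medium") {
  vals <- c(glc = glc, gln = gln, lac = lac)
  if (any(!is.finite(vals)) || any(vals < 0))
    abort("medium concentrations must be finite and >= 0",
          class = "perfusim_invalid_parameter")
  if (!is.finite(osm) || osm <= 0)
    abort("medium osmolality must be > 0", class = "perfusim_invalid_parameter")
  structure(list(glc = glc, gln = gln, lac = lac, osm = osm,
                 label = as.character(label)),
            class = "medium_composition")
}

#' @export
print.medium_composition <- function(x, ...) {
  cat(sprintf("<medium_composition> %s: glc=%g mM gln=%g mM lac=%g mM osm=%g mOsm/kg\n",
              x$label, x$glc, x$gln, x$lac, x$osm))
  invisible(x)
}

#' Perfusion feed schedule
#'
#' A piecewise-constant perfusion-rate schedule: contiguous day intervals,
#' each with a rate in working volumes per day (vvd, the dilution rate F/V)
#' and the feed medium applied over the interval. The reference 7-day
#' schedule (rates 0, 1, 1.5, 3, 4, 6, 7 vvd) is available via
#' `load_builtin("table3_schedule")`.
#'
#' @param start_day,end_day numeric vectors of interval bounds (days);
#'   intervals must be contiguous and start at day 0.
#' @param rate perfusion rate per interval, working volumes per day (>= 0).
#' @param medium a list of [medium_composition()] objects, one per interval
#'   (a single medium is recycled).
#' @return A `feed_schedule`: a tibble with columns `start_day`, `end_day`,
#'   `rate` and a `medium` list-column.
#' @examples
#' m <- medium_composition(glc = 34.15, gln = 4.5, osm = 337.5, label = "feed I")
#' feed_schedule(0:1, 1:2, rate = c(0, 1), medium = list(m))
#' @export
feed_schedule <- function(start_day, end_day, rate, medium) {
  n <- length(start_day)
  if (length(end_day) != n || length(rate) != n)
    abort("start_day, end_day and rate must have equal length",
          class = "perfusim_invalid_parameter")
  if (inherits(medium, "medium_composition")) medium <- list(medium)
  if (length(medium) == 1L) medium <- rep(medium, n)
  if (length(medium) != n)
    abort("medium must have length 1 or length(start_day)",
          class = "perfusim_invalid_parameter")
  if (!all(map_dbl(seq_len(n), ~ inherits(medium[[.x]], "medium_composition")) == 1))
    abort("medium must contain medium_composition objects",
          class = "perfusim_invalid_parameter")
  ord <- order(start_day)
  start_day <- start_day[ord]; end_day <- end_day[ord]
  rate <- rate[ord]; medium <- medium[ord]
  if (start_day[1] != 0)
    abort("feed schedule must start at day 0", class = "perfusim_invalid_parameter")
  if (any(end_day <= start_day))
    abort("each segment must have end_day > start_day",
          class = "perfusim_invalid_parameter")
  if (n > 1 && any(abs(start_day[-1] - end_day[-n]) > 1e-12))
    abort("feed schedule segments must be contiguous and non-overlapping",
          class = "perfusim_invalid_parameter")
  if (any(rate < 0))
    abort("perfusion rates must be >= 0", class = "perfusim_invalid_parameter")
  out <- tibble(start_day = as.numeric(start_day),
                end_day = as.numeric(end_day),
                rate = as.numeric(rate),
                medium = medium)
  class(out) <- c("feed_schedule", class(out))
  out
}

#' Look up the feed rate and medium in effect at a time
#'
#' The schedule is right-open on each segment: at an interior boundary the
#' incoming segment applies (the convention used when daily rate changes are
#' entered at sampling time).
#'
#' @param schedule a [feed_schedule()].
#' @param t time (day).
#' @return A list with elements `rate` (vvd) and `medium`
#'   ([medium_composition()]); rate 0 and `NULL` medium outside the schedule.
#' @export
schedule_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "feed_schedule"), length(t) == 1L)
  i <- which(t >= schedule$start_day & t < schedule$end_day)
  if (length(i) == 0L) {
    # allow exact right endpoint of the final segment
    if (abs(t - schedule$end_day[nrow(schedule)]) <= 1e-12) i <- nrow(schedule)
    else return(list(rate = 0, medium = NULL))
  }
  i <- i[1]
  list(rate = schedule$rate[i], medium = schedule$medium[[i]])
}

#' Reactor geometry
#'
#' Describes a stirred-tank system for the scale-up calculators: impeller
#' diameter, usable working-volume range, and (where a fitted
#' volume-to-speed law exists) its cube-root speed constant plus the
#' reference-volume operating speed window. Built-ins: `"dasbox"`
#' (34 mm pitched-blade impeller, 100-250 mL, constant 150.5, 50-120 rpm at
#' 0.15 L) and `"bioblock"` (53 mm impeller, 300-1000 mL, constant 76.5).
#'
#' @param name system identifier.
#' @param impeller_diameter impeller outer diameter (m).
#' @param volume_range length-2 numeric, usable working volume (L), ascending.
#' @param speed_constant fitted constant of the cube-root law
#'   `N = constant * V^(1/3)` (rpm L^-1/3), or `NA` when none is fitted.
#' @param reference_volume volume (L) at which the operating speed window is
#'   stated.
#' @param min_speed_at_ref,max_speed_at_ref operating window (rpm) at the
#'   reference volume, or `NA`.
#' @return An object of class `reactor_geometry` (a named list).
#' @export
reactor_geometry <- function(name, impeller_diameter, volume_range,
                             speed_constant = NA_real_,
                             reference_volume = NA_real_,
                             min_speed_at_ref = NA_real_,
                             max_speed_at_ref = NA_real_) {
  if (!is.numeric(impeller_diameter) || impeller_diameter <= 0)
    abort("impeller_diameter must be > 0", class = "perfusim_invalid_parameter")
  if (length(volume_range) != 2L || diff(volume_range) <= 0)
    abort("volume_range must be an ascending length-2 numeric",
          class = "perfusim_invalid_parameter")
  if (is.finite(min_speed_at_ref) && is.finite(max_speed_at_ref) &&
      min_speed_at_ref >= max_speed_at_ref)
    abort("min_speed_at_ref must be < max_speed_at_ref",
          class = "perfusim_invalid_parameter")
  structure(list(name = name, impeller_diameter = impeller_diameter,
                 volume_range = as.numeric(volume_range),
                 speed_constant = speed_constant,
                 reference_volume = reference_volume,
                 min_speed_at_ref = min_speed_at_ref,
                 max_speed_at_ref = max_speed_at_ref),
            class = "reactor_geometry")
}

#' @export
print.reactor_geometry <- function(x, ...) {
  cat(sprintf("<reactor_geometry> %s: D=%g m, V in [%g, %g] L",
              x$name, x$impeller_diameter, x$volume_range[1], x$volume_range[2]))
  if (is.finite(x$speed_constant))
    cat(sprintf(", N = %g * V^(1/3) rpm", x$speed_constant))
  cat("\n")
  invisible(x)
}

# --- built-in fixtures -------------------------------------------------------

# Basal DMEM/F12-derived glucose and glutamine of the E8 basis are not part of
# the printed recipes; 17.5 mM glucose and 2.5 mM glutamine are the
# conventional DMEM/F12 values and are configurable through the constructors.
.builtin_media <- function(basal_glc = 17.5) {
  list(
    basis = medium_composition(glc = basal_glc, gln = 2.5, lac = 0,
                               osm = 317.5, label = "E8 suspension"),
    # feed I: + 30 g glucose / 10 L = 16.65 mM; glutamine 4.5 mM total
    feed_I = medium_composition(glc = basal_glc + 16.65, gln = 4.5, lac = 0,
                                osm = 337.5, label = "E8 full feed I"),
    # feed II: + 45 g glucose / 10 L = 24.98 mM; glutamine 5.0 mM total
    feed_II = medium_composition(glc = basal_glc + 24.98, gln = 5.0, lac = 0,
                                 osm = 352.5, label = "E8 full feed II")
  )
}

#' Built-in fixtures: parameters, schedule, media, reactor geometries
#'
#' @param name one of `"table1_params"` (exemplary kinetic parameters with
#'   the shipped calibrated auxiliaries), `"table3_schedule"` (the reference
#'   7-day perfusion schedule with its feed media), `"media_e8"` (named list
#'   of the three media), `"dasbox"`, `"bioblock"` (reactor geometries).
#' @return The corresponding typed object.
#' @examples
#' load_builtin("table3_schedule")
#' load_builtin("media_e8")$feed_II$gln
#' @export
load_builtin <- function(name) {
  known <- c("table1_params", "table3_schedule", "media_e8", "dasbox", "bioblock")
  if (!is.character(name) || length(name) != 1L || !name %in% known)
    abort(paste0("unknown builtin; available: ", paste(known, collapse = ", ")),
          class = "perfusim_unknown_builtin")
  media <- .builtin_media()
  switch(name,
    table1_params = kinetic_parameters(),
    media_e8 = media,
    table3_schedule = feed_schedule(
      start_day = 0:6, end_day = 1:7,
      rate = c(0, 1, 1.5, 3, 4, 6, 7),
      medium = c(list(media$basis), rep(list(media$feed_I), 3),
                 rep(list(media$feed_II), 3))
    ),
    dasbox = reactor_geometry(
      name = "DASbox", impeller_diameter = 0.034,
      volume_range = c(0.100, 0.250), speed_constant = 150.5,
      reference_volume = 0.150, min_speed_at_ref = 50, max_speed_at_ref = 120
    ),
    bioblock = reactor_geometry(
      name = "DASGIP Bioblock", impeller_diameter = 0.053,
      volume_range = c(0.300, 1.000), speed_constant = 76.5
    )
  )
}
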
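#' Measurement-noise model for synthetic process data
#'
#' Emulates the repeatability of daily bioreactor sampling: multiplicative
#' lognormal noise on the cell count (automated trypan-blue counting),
#' additive Gaussian noise on supernatant metabolite assays, osmometry and
#' image-based mean aggregate diameter. The defaults are engineering
#' defaults for those instruments, not literature values.
#'
#' @param cv_X coefficient of variation of the multiplicative lognormal
#'   cell-density noise (dimensionless).
#' @param sd_met additive SD per metabolite concentration (mM).
#' @param sd_osm additive SD of osmolality (mOsm/kg).
#' @param sd_agg additive SD of mean aggregate diameter (um).
#' @param seed integer RNG seed; identical seed and inputs give an
#'   identical dataset.
#' @return An object of class `noise_model`.
#' @examples
#' noise_model(cv_X = 0.05, seed = 7)
#' @export
noise_model <- function(cv_X = 0.05, sd_met = 0.3, sd_osm = 3, sd_agg = 10,
                        seed = 1L) {
  vals <- c(cv_X = cv_X, sd_met = sd_met, sd_osm = sd_osm, sd_agg = sd_agg)
  if (any(!is.finite(vals)) || any(vals < 0))
    abort("noise SDs must be finite and >= 0", class = "perfusim_invalid_parameter")
  structure(list(cv_X = cv_X, sd_met = sd_met, sd_osm = sd_osm,
                 sd_agg = sd_agg, seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate a synthetic sampled process dataset
#'
#' Runs the simulator, samples the trajectory at the requested times,
#' applies the measurement-noise model, clamps measurements at zero (cell
#' density is redrawn on a non-positive draw; the redraw count is attached
#' as an attribute) and attaches the scheduled flow in effect after each
#' sampling time. The result is a drop-in stand-in for a daily-sampled
#' wet-lab process table, suitable for exercising the rate estimators and
#' the model-evaluation statistics end to end.
#'
#' @param p a [kinetic_parameters()] object.
#' @param schedule a [feed_schedule()].
#' @param initial a [process_state()]; default: the reference inoculation
#'   (0.5e6 cells/mL in 150 mL of E8 suspension medium).
#' @param sampling_times sampling times (day), within the simulated span.
#' @param noise a [noise_model()].
#' @param dt_out simulator output grid (day); sampling times are added to it.
#' @return A `process_series` tibble with columns `t`, `X` (cells/L),
#'   `viability`, `glc`, `lac`, `gln`, `osm`, `d_agg`, `F` (L/day), `V` (L),
#'   with the noise-free trajectory, parameters and schedule attached as
#'   attributes.
#' @examples
#' obs <- synthesize_process(sampling_times = 0:7,
#'                           noise = noise_model(cv_X = 0.05, seed = 42))
#' estimate_rates(obs)
#' @export
synthesize_process <- function(p = kinetic_parameters(),
                               schedule = load_builtin("table3_schedule"),
                               initial = NULL,
                               sampling_times = 0:7,
                               noise = noise_model(),
                               dt_out = 0.05) {
  stopifnot(inherits(noise, "noise_model"))
  if (is.null(initial)) {
    media <- .builtin_media()
    initial <- process_state(t = 0, X = 0.5e9, glc = media$basis$glc,
                             gln = media$basis$gln, lac = 0,
                             osm = media$basis$osm, d_agg = p$d_cell, V = 0.15)
  }
  t_end <- max(sampling_times)
  if (min(sampling_times) < initial$t - 1e-12)
    abort("sampling times must lie within the simulated span",
          class = "perfusim_invalid_parameter")
  traj <- simulate_process(initial, p, schedule, t_end = t_end, dt_out = dt_out)
  at <- function(v) approx(traj$t, traj[[v]], xout = sampling_times)$y
  clean <- tibble(
    t = as.numeric(sampling_times),
    X = at("X"), glc = at("glc"), lac = at("lac"), gln = at("gln"),
    osm = at("osm"), d_agg = at("d_agg")
  )

  n <- nrow(clean)
  resampled <- 0L
  withr_seed <- noise$seed
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(withr_seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)

  X <- clean$X
  if (noise$cv_X > 0) {
    sdlog <- sqrt(log(1 + noise$cv_X^2))
    X <- clean$X * stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    while (any(X <= 0)) {   # lognormal draws are positive; guard is belt-and-braces
      i <- which(X <= 0)
      X[i] <- clean$X[i] * stats::rlnorm(length(i), -sdlog^2 / 2, sdlog)
      resampled <- resampled + length(i)
    }
  }
  addnoise <- function(v, s) pmax(0, v + stats::rnorm(n, 0, s))
  out <- tibble(
    t = clean$t,
    X = X,
    viability = 1,
    glc = addnoise(clean$glc, noise$sd_met),
    lac = addnoise(clean$lac, noise$sd_met),
    gln = addnoise(clean$gln, noise$sd_met),
    osm = addnoise(clean$osm, noise$sd_osm),
    d_agg = addnoise(clean$d_agg, noise$sd_agg),
    F = map_dbl(clean$t, ~ schedule_at(schedule, .x)$rate) * initial$V,
    V = initial$V
  )
  structure(out, class = c("process_series", class(tibble())),
            trajectory = traj, parameters = p, schedule = schedule,
            noise = noise, n_resampled = resampled)
}
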
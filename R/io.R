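#' Read and write the process-data CSV dialect
#'
#' One canonical, unit-bearing CSV layout for sampled process data
#' (comma-separated, dot decimal, UTF-8, mandatory header):
#' `t_d, X_cells_per_mL, viability_pct, glc_mM, lac_mM, gln_mM,
#' osm_mOsm_kg, agg_diameter_um, feed_rate_vvd, volume_L`.
#' Only `t_d` and `X_cells_per_mL` are required; unknown columns are
#' preserved on round-trip. Cell density is converted cells/mL -> cells/L
#' exactly once, at this boundary; a column named in any other unit (e.g.
#' `X_cells_per_L`) is a schema error, never silently rescaled -- the
#' cell-specific rate estimators are off by a factor 1000 otherwise.
#'
#' @param path file path.
#' @return `read_process_csv()`: a `process_series` tibble in internal units
#'   (`t` day, `X` cells/L, `glc`/`lac`/`gln` mM, `osm` mOsm/kg, `d_agg` um,
#'   `F` L/day, `V` L, `viability` fraction). `write_process_csv()`: `path`,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' obs <- synthesize_process(sampling_times = 0:3)
#' write_process_csv(obs, f)
#' read_process_csv(f)
#' @export
read_process_csv <- function(path) {
  if (!file.exists(path))
    abort(paste0("no such file: ", path), class = "perfusim_io_error")
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("X_cells_per_L" %in% names(raw))
    abort("column `X_cells_per_L` found: this dialect requires `X_cells_per_mL` (cells/mL); rescale explicitly",
          class = "perfusim_schema_error")
  required <- c("t_d", "X_cells_per_mL")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    abort(paste0("missing required columns: ", paste(missing_cols, collapse = ", ")),
          class = "perfusim_schema_error")

  problems <- character(0)
  note <- function(row, col, why) problems <<- c(problems, sprintf("row %d, %s: %s", row, col, why))
  for (i in seq_len(nrow(raw))) {
    if (!is.na(raw$X_cells_per_mL[i]) && raw$X_cells_per_mL[i] < 0)
      note(i, "X_cells_per_mL", "negative cell density")
  }
  if (is.unsorted(raw$t_d, strictly = TRUE))
    problems <- c(problems, "t_d: times must be strictly increasing")
  if (length(problems) > 0)
    abort(paste0("invalid process data:\n", paste("-", problems, collapse = "\n")),
          class = "perfusim_schema_error")

  grab <- function(col) if (col %in% names(raw)) raw[[col]] else NA_real_
  known <- c("t_d", "X_cells_per_mL", "viability_pct", "glc_mM", "lac_mM",
             "gln_mM", "osm_mOsm_kg", "agg_diameter_um", "feed_rate_vvd",
             "volume_L")
  V <- grab("volume_L")
  out <- tibble(
    t = raw$t_d,
    X = raw$X_cells_per_mL * 1000,          # cells/mL -> cells/L
    viability = grab("viability_pct") / 100,
    glc = grab("glc_mM"), lac = grab("lac_mM"), gln = grab("gln_mM"),
    osm = grab("osm_mOsm_kg"), d_agg = grab("agg_diameter_um"),
    F = grab("feed_rate_vvd") * V, V = V
  )
  extra <- raw[setdiff(names(raw), known)]
  out <- bind_cols(out, extra)
  structure(out, class = c("process_series", class(tibble())))
}

#' @param series a `process_series` tibble (internal units).
#' @rdname read_process_csv
#' @export
write_process_csv <- function(series, path) {
  series <- as_tibble(series)
  known <- c("t", "X", "viability", "glc", "lac", "gln", "osm", "d_agg", "F", "V")
  out <- tibble(
    t_d = series$t,
    X_cells_per_mL = series$X / 1000,
    viability_pct = if ("viability" %in% names(series)) series$viability * 100 else NA_real_,
    glc_mM = series$glc, lac_mM = series$lac, gln_mM = series$gln,
    osm_mOsm_kg = series$osm, agg_diameter_um = series$d_agg,
    feed_rate_vvd = series$F / series$V, volume_L = series$V
  )
  out <- bind_cols(out, series[setdiff(names(series), known)])
  readr::write_csv(round_numerics(out), path, progress = FALSE)
  invisible(path)
}

# the dialect writes numerics at 12 significant digits: enough for any
# measured process quantity, and stable under write -> read -> write
round_numerics <- function(df) {
  df[] <- lapply(df, function(x) if (is.numeric(x)) signif(x, 12) else x)
  df
}

#' Write a simulated trajectory as CSV
#'
#' Columns `t_d, X_cells_per_mL, glc_mM, lac_mM, gln_mM, osm_mOsm_kg,
#' agg_diameter_um, feed_rate_vvd` (cell density reported per mL for bench
#' parity).
#'
#' @param traj a `perfusion_trajectory`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- tibble(
    t_d = traj$t, X_cells_per_mL = traj$X / 1000,
    glc_mM = traj$glc, lac_mM = traj$lac, gln_mM = traj$gln,
    osm_mOsm_kg = traj$osm, agg_diameter_um = traj$d_agg,
    feed_rate_vvd = traj$F / traj$V
  )
  readr::write_csv(round_numerics(out), path, progress = FALSE)
  invisible(path)
}

#' Write rate estimates as CSV
#'
#' Columns `t_start_d, t_end_d, regime, mu_per_d, q_glc, q_lac, q_gln,
#' reason` (q in mmol cell^-1 day^-1).
#'
#' @param rates a `rate_estimates` tibble from [estimate_rates()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_rates_csv <- function(rates, path) {
  out <- tibble(
    t_start_d = rates$t_start, t_end_d = rates$t_end, regime = rates$regime,
    mu_per_d = rates$mu,
    q_glc = if ("q_glc" %in% names(rates)) rates$q_glc else NA_real_,
    q_lac = if ("q_lac" %in% names(rates)) rates$q_lac else NA_real_,
    q_gln = if ("q_gln" %in% names(rates)) rates$q_gln else NA_real_,
    reason = rates$reason
  )
  readr::write_csv(round_numerics(out), path, progress = FALSE)
  invisible(path)
}

#' Read a process configuration file
#'
#' YAML (or JSON) configuration with sections `parameters`, `media` (named
#' compositions with fields `glc`, `gln`, `lac`, `osm`), `schedule` (list of
#' `{start_day, end_day, rate, medium}` referencing media by name),
#' `initial_state`, and optional `integration` (`t_end`, `dt_out`) and
#' `calibration` (`target_X7`, grid bounds) sections. Any omitted parameter
#' falls back to the shipped defaults.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return A list with elements `parameters` ([kinetic_parameters()]),
#'   `media`, `schedule` ([feed_schedule()]), `initial`
#'   ([process_state()]), `integration`, `calibration`, and `digest` (a
#'   stable hash of the parsed content, recorded in provenance logs).
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    abort(paste0("no such file: ", path), class = "perfusim_io_error")
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)

  p <- do.call(kinetic_parameters, as.list(cfg$parameters %||% list()))
  media <- if (is.null(cfg$media)) .builtin_media() else
    imap(cfg$media, function(m, nm)
      medium_composition(glc = m$glc, gln = m$gln, lac = m$lac %||% 0,
                         osm = m$osm, label = m$label %||% nm))
  schedule <- if (is.null(cfg$schedule)) load_builtin("table3_schedule") else {
    segs <- cfg$schedule
    feed_schedule(
      start_day = map_dbl(segs, "start_day"),
      end_day = map_dbl(segs, "end_day"),
      rate = map_dbl(segs, "rate"),
      medium = map(segs, function(s) {
        nm <- s$medium %||% names(media)[1]
        if (!nm %in% names(media))
          abort(paste0("schedule references unknown medium: ", nm),
                class = "perfusim_schema_error")
        media[[nm]]
      })
    )
  }
  init_cfg <- lapply(cfg$initial_state %||% list(), as.numeric)
  basis <- media[[1]]
  initial <- process_state(
    t = init_cfg$t %||% 0,
    X = init_cfg$X_cells_per_mL %||% 0.5e6,
    glc = init_cfg$glc %||% basis$glc,
    gln = init_cfg$gln %||% basis$gln,
    lac = init_cfg$lac %||% 0,
    osm = init_cfg$osm %||% basis$osm,
    d_agg = init_cfg$d_agg %||% p$d_cell,
    V = init_cfg$V %||% 0.15
  )
  initial$X <- initial$X * 1000   # config states cells/mL; internal cells/L
  integration <- modifyList(list(t_end = 7, dt_out = 0.05),
                            as.list(cfg$integration %||% list()))
  digest <- config_digest(cfg)
  list(parameters = p, media = media, schedule = schedule, initial = initial,
       integration = integration, calibration = cfg$calibration,
       digest = digest)
}

# stable content hash of a parsed config (md5 of its canonical JSON)
config_digest <- function(cfg) {
  canonical <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(canonical, f)
  unname(tools::md5sum(f))
}
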
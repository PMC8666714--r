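# shared fixtures built in code

ref_initial <- function(V = 0.15, d_agg = 15) {
  media <- load_builtin("media_e8")
  process_state(t = 0, X = 0.5e9, glc = media$basis$glc, gln = media$basis$gln,
                lac = 0, osm = media$basis$osm, d_agg = d_agg, V = V)
}

# single-segment schedule helper
flat_schedule <- function(rate, medium, t_end = 7) {
  feed_schedule(0, t_end, rate = rate, medium = medium)
}

# parameters with every growth factor pinned at (numerically) 1 and inert
# metabolism, for closed-form growth checks
saturated_parameters <- function(mu_max = 1.35) {
  kinetic_parameters(mu_max = mu_max,
                     q_Glc_max = 0, q_Lac_max = 0, q_Gln_max = 0,
                     k_osm = 0, t_agg = 1e6)
}

saturated_state <- function(p, V = 1) {
  process_state(t = 0, X = 1e9, glc = 1e9, gln = 1e9, lac = 0,
                osm = p$osm_ref, d_agg = 0, V = V)
}

# time-average of a trajectory column over [t1, t2] (trapezoid); the
# independent oracle for interval-averaged true rates
traj_interval_mean <- function(traj, col, t1, t2) {
  keep <- traj$t >= t1 - 1e-9 & traj$t <= t2 + 1e-9
  tt <- traj$t[keep]; y <- traj[[col]][keep]
  sum(diff(tt) * (head(y, -1) + tail(y, -1)) / 2) / (tt[length(tt)] - tt[1])
}
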
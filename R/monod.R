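#' Monod limitation and inhibition factors
#'
#' The two hyperbolic building blocks of the growth model. `monod_limitation()`
#' is the classical saturating substrate dependence `c/(K + c)`, rising from 0
#' at no substrate toward 1 at saturation; `monod_inhibition()` is the
#' Monod-like inhibitory form `K/(K + c)`, equal to 1 with no inhibitor and
#' falling toward 0 as the inhibitor accumulates.
#'
#' @param c substrate (or inhibitor) level, >= 0; vectorised.
#' @param K half-effect constant in the same units, > 0.
#' @return A factor in `[0, 1)` (limitation) or `(0, 1]` (inhibition).
#' @examples
#' monod_limitation(1.5, 1.5)   # half-saturation: 0.5
#' monod_inhibition(118, 50)    # heavy lactate load
#' @export
monod_limitation <- function(c, K) {
  check_monod_args(c, K)
  c / (K + c)
}

#' @rdname monod_limitation
#' @export
monod_inhibition <- function(c, K) {
  check_monod_args(c, K)
  K / (K + c)
}

check_monod_args <- function(c, K) {
  if (!is.numeric(c) || any(!is.finite(c)) || any(c < 0))
    abort("concentration must be finite and >= 0",
          class = "perfusim_invalid_parameter")
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    abort("Monod constant K must be a single finite value > 0",
          class = "perfusim_invalid_parameter")
  invisible(NULL)
}

#' Effective specific growth rate of the Monod model
#'
#' Composes the five rate-modifying process variables multiplicatively:
#' glucose and glutamine limit (`c/(K+c)`), while lactate, osmolality excess
#' above `osm_ref` and aggregate radius inhibit (`K/(K+c)`):
#' \deqn{\mu_{eff} = \mu_{max}\,\frac{Glc}{K_{Glc}+Glc}\,
#'   \frac{Gln}{K_{Gln}+Gln}\, \frac{K_{Lac}}{K_{Lac}+Lac}\,
#'   \frac{K_{Osm}}{K_{Osm}+\max(0, Osm-Osm_{ref})}\,
#'   \frac{K_{Agg}}{K_{Agg}+d_{agg}/2}}
#'
#' @param state a one-row data frame or named list with `glc`, `gln`, `lac`,
#'   `osm`, `d_agg` (see [process_state()]).
#' @param p a [kinetic_parameters()] object.
#' @return Specific growth rate (1/day), in `[0, mu_max]`.
#' @examples
#' p <- kinetic_parameters()
#' specific_growth_rate(
#'   process_state(X = 5e8, glc = 17.5, gln = 2.5, lac = 0,
#'                 osm = 317.5, d_agg = 15, V = 0.15), p)
#' @export
specific_growth_rate <- function(state, p) {
  stopifnot(inherits(p, "kinetic_parameters"))
  p$mu_max *
    monod_limitation(state$glc, p$K_Glc) *
    monod_limitation(state$gln, p$K_Gln) *
    monod_inhibition(state$lac, p$K_Lac) *
    monod_inhibition(pmax(0, state$osm - p$osm_ref), p$K_Osm) *
    monod_inhibition(state$d_agg / 2, p$K_Agg)
}

#' Nucleation-based aggregate diameter at onset
#'
#' An optional alternative to the calibrated `d_agg_init` default: treats a
#' fraction `agg_f` of the cells present at the onset time as packed into
#' aggregates nucleated by a fraction `agg_g` of the inoculated cells, so the
#' mean diameter at onset is
#' `d_cell * (agg_f * X_onset / (packing * agg_g * X0))^(1/3)`.
#' This is one consistent reading of the cell-line-dependent aggregation
#' coefficients; the shipped default pipeline uses the calibrated constant
#' instead.
#'
#' @param p a [kinetic_parameters()] object.
#' @param X_onset viable cell density at the onset time (cells/L).
#' @param X0 inoculation density (cells/L).
#' @return Mean aggregate diameter (um).
#' @export
aggregate_onset_diameter <- function(p, X_onset, X0) {
  stopifnot(inherits(p, "kinetic_parameters"), X_onset > 0, X0 > 0)
  p$d_cell * (p$agg_f * X_onset / (p$packing * p$agg_g * X0))^(1 / 3)
}
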
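#' Logarithmic mean
#'
#' `(a - b) / (ln a - ln b)`, the correct average of an exponentially
#' changing quantity over a sampling interval; it underlies all the pairwise
#' cell-specific rate estimators. The equal-value limit is handled
#' analytically (returns `a` when the relative gap is <= 1e-12). Non-positive
#' inputs are a domain error: no silent arithmetic-mean fallback is applied.
#'
#' @param a,b positive quantities (vectorised).
#' @return The logarithmic mean, same units as the inputs.
#' @examples
#' log_mean(0.5e9, 1.0e9)   # 0.5e9 / ln 2
#' @export
log_mean <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || any(!is.finite(a)) || any(!is.finite(b)))
    abort("log_mean requires finite numeric inputs", class = "perfusim_domain_error")
  if (any(a <= 0) || any(b <= 0))
    abort("log_mean is undefined for non-positive values", class = "perfusim_domain_error")
  # log(a) - log(b) == log1p((a - b)/b): the log1p form avoids the
  # catastrophic cancellation of subtracting two nearly equal logarithms
  out <- ifelse(abs(a - b) <= 1e-12 * pmax(a, b), a,
                (a - b) / log1p((a - b) / b))
  as.numeric(out)
}

check_interval <- function(x1, x2) {
  if (x2$t <= x1$t)
    abort("sample times must be strictly increasing", class = "perfusim_ordering_error")
  if (x1$X <= 0 || x2$X <= 0)
    abort("cell densities must be positive for the log-mean", class = "perfusim_domain_error")
  invisible(NULL)
}

need_field <- function(rec, field) {
  v <- rec[[field]]
  if (is.null(v) || is.na(v))
    abort(sprintf("required metabolite column `%s` is missing or NA", field),
          class = "perfusim_missing_field")
  v
}

#' Cell-specific growth rate from two samples
#'
#' `mu = (X2 - X1)/(t2 - t1) * 1/log_mean(X2, X1)`, which is algebraically
#' `ln(X2/X1) / (t2 - t1)`.
#'
#' @param x1,x2 one-row data frames (or named lists) with at least `t` (day)
#'   and `X` (cells/L), `x2` later than `x1`.
#' @return Specific growth rate (1/day).
#' @examples
#' growth_rate_estimate(list(t = 0, X = 0.5e9), list(t = 1, X = 1e9)) # ln 2
#' @export
growth_rate_estimate <- function(x1, x2) {
  check_interval(x1, x2)
  (x2$X - x1$X) / (x2$t - x1$t) / log_mean(x2$X, x1$X)
}

#' Cell-specific substrate and waste rates from two samples
#'
#' Pairwise estimators of per-cell metabolite turnover between consecutive
#' samples, normalised by the log-mean cell density. Batch forms apply to
#' intervals without medium exchange; perfusion forms add the dilution term
#' `F/V * (c_mean - c_feed)` (substrates) or `F/V * c_mean` (wastes, feed
#' assumed waste-free), with the in-vessel mean concentration taken as the
#' log-mean of the interval endpoints. Signs follow bench convention:
#' consumption-positive for substrates, production-positive for wastes.
#'
#' @param s1,s2,w1,w2 one-row data frames/named lists with `t`, `X`, the
#'   metabolite column named by `metabolite`, and (perfusion forms) `F`
#'   (L/day, in effect over the interval) and `V` (L).
#' @param metabolite name of the metabolite column (e.g. `"glc"`, `"lac"`).
#' @param feed a [medium_composition()] giving the feed concentration of the
#'   substrate.
#' @return Cell-specific rate (mmol cell^-1 day^-1).
#' @examples
#' substrate_rate_batch(list(t = 0, X = 1e9, glc = 20),
#'                      list(t = 1, X = 1e9, glc = 10), "glc")
#' @export
substrate_rate_batch <- function(s1, s2, metabolite) {
  check_interval(s1, s2)
  c1 <- need_field(s1, metabolite); c2 <- need_field(s2, metabolite)
  -((c2 - c1) / (s2$t - s1$t)) / log_mean(s2$X, s1$X)
}

#' @rdname substrate_rate_batch
#' @export
substrate_rate_perfusion <- function(s1, s2, metabolite, feed) {
  check_interval(s1, s2)
  F_rate <- need_field(s1, "F")
  if (F_rate <= 0)
    abort("no perfusion on this interval (F = 0); use the batch form",
          class = "perfusim_wrong_regime")
  stopifnot(inherits(feed, "medium_composition"))
  c1 <- need_field(s1, metabolite); c2 <- need_field(s2, metabolite)
  if (c1 <= 0 || c2 <= 0)
    abort("substrate log-mean undefined at non-positive concentration",
          class = "perfusim_domain_error")
  V <- need_field(s1, "V")
  c_bar <- log_mean(c2, c1)
  c_feed <- feed[[metabolite]]
  -((c2 - c1) / (s2$t - s1$t) + (F_rate / V) * (c_bar - c_feed)) /
    log_mean(s2$X, s1$X)
}

#' @rdname substrate_rate_batch
#' @export
waste_rate_batch <- function(w1, w2, metabolite) {
  check_interval(w1, w2)
  c1 <- need_field(w1, metabolite); c2 <- need_field(w2, metabolite)
  ((c2 - c1) / (w2$t - w1$t)) / log_mean(w2$X, w1$X)
}

#' @rdname substrate_rate_batch
#' @export
waste_rate_perfusion <- function(w1, w2, metabolite) {
  check_interval(w1, w2)
  F_rate <- need_field(w1, "F")
  if (F_rate <= 0)
    abort("no perfusion on this interval (F = 0); use the batch form",
          class = "perfusim_wrong_regime")
  c1 <- need_field(w1, metabolite); c2 <- need_field(w2, metabolite)
  if (c1 <= 0 || c2 <= 0)
    abort("waste log-mean undefined at non-positive concentration",
          class = "perfusim_domain_error")
  V <- need_field(w1, "V")
  c_bar <- log_mean(c2, c1)
  ((c2 - c1) / (w2$t - w1$t) + (F_rate / V) * c_bar) / log_mean(w2$X, w1$X)
}

#' Estimate all cell-specific rates along a process time series
#'
#' Walks consecutive sampling intervals, picks the batch or perfusion
#' estimator by the flow in effect at interval start (step-function
#' convention: the record opening the interval carries the flow applied
#' until the next sample), and returns one tidy row per interval. Intervals
#' where a required log-mean is undefined (a non-positive concentration at
#' an endpoint, e.g. lactate at inoculation) yield `NA` for that metabolite
#' with a reason code -- never a silent drop or an arithmetic-mean fallback.
#'
#' @param series a tibble of samples in the layout returned by
#'   [read_process_csv()] or [synthesize_process()]: columns `t`, `X`
#'   (cells/L), `glc`, `lac`, `gln`, `F` (L/day), `V` (L).
#' @param metabolites named character: which columns to treat as substrates
#'   (`"substrate"`) or wastes (`"waste"`). Default glucose and glutamine as
#'   substrates, lactate as waste.
#' @param feed_schedule optional [feed_schedule()]; when given, the feed
#'   composition for perfused intervals is the medium in effect at interval
#'   start. Required if any perfused interval involves a substrate.
#' @return A `rate_estimates` tibble: `t_start`, `t_end`, `regime`
#'   (`"batch"`/`"perfusion"`), `mu`, one `q_<metabolite>` column per
#'   requested metabolite, and `reason` (NA or a semicolon-separated list of
#'   per-metabolite degeneracy codes).
#' @examples
#' traj <- simulate_reference()
#' obs <- synthesize_process(sampling_times = 0:7,
#'                           noise = noise_model(cv_X = 0, sd_met = 0))
#' estimate_rates(obs)
#' @export
estimate_rates <- function(series,
                           metabolites = c(glc = "substrate",
                                           gln = "substrate",
                                           lac = "waste"),
                           feed_schedule = NULL) {
  feed_schedule <- feed_schedule %||% attr(series, "schedule")
  series <- as_tibble(series)
  need <- c("t", "X", names(metabolites), "F", "V")
  missing_cols <- setdiff(need, names(series))
  if (length(missing_cols) > 0)
    abort(paste0("missing required columns: ", paste(missing_cols, collapse = ", ")),
          class = "perfusim_missing_field")
  if (nrow(series) < 2)
    abort("need at least two samples", class = "perfusim_domain_error")
  if (is.unsorted(series$t, strictly = TRUE))
    abort("sample times must be strictly increasing", class = "perfusim_ordering_error")

  rows <- map(seq_len(nrow(series) - 1L), function(i) {
    r1 <- series[i, ]; r2 <- series[i + 1L, ]
    perfused <- is.finite(r1$F) && r1$F > 0
    regime <- if (perfused) "perfusion" else "batch"
    reasons <- character(0)
    mu <- if (r1$X > 0 && r2$X > 0) growth_rate_estimate(r1, r2) else {
      reasons <- c(reasons, "X:log-mean domain"); NA_real_
    }
    qs <- imap(as.list(metabolites), function(role, met) {
      ok_X <- r1$X > 0 && r2$X > 0
      c1 <- r1[[met]]; c2 <- r2[[met]]
      if (!ok_X || anyNA(c(c1, c2))) {
        reasons <<- c(reasons, paste0(met, ":missing-or-domain"))
        return(NA_real_)
      }
      if (!perfused) {
        if (role == "substrate") substrate_rate_batch(r1, r2, met)
        else waste_rate_batch(r1, r2, met)
      } else {
        if (c1 <= 0 || c2 <= 0) {
          reasons <<- c(reasons, paste0(met, ":log-mean domain"))
          return(NA_real_)
        }
        if (role == "substrate") {
          if (is.null(feed_schedule))
            abort("feed_schedule is required to estimate substrate rates on perfused intervals",
                  class = "perfusim_missing_field")
          feed <- schedule_at(feed_schedule, r1$t)$medium
          substrate_rate_perfusion(r1, r2, met, feed)
        } else {
          waste_rate_perfusion(r1, r2, met)
        }
      }
    })
    out <- tibble(t_start = r1$t, t_end = r2$t, regime = regime, mu = mu)
    for (met in names(qs)) out[[paste0("q_", met)]] <- qs[[met]]
    out$reason <- if (length(reasons) == 0) NA_character_ else
      paste(reasons, collapse = "; ")
    out
  })
  out <- bind_rows(rows)
  structure(out, class = c("rate_estimates", class(tibble())),
            metabolites = metabolites)
}
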
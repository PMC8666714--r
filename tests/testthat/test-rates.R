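test_that("log mean handles the textbook cases and its analytic limit", {
  expect_equal(log_mean(2, 2), 2)
  expect_equal(log_mean(1, exp(1)), exp(1) - 1)
  expect_equal(log_mean(0.5e9, 1.0e9), 0.5e9 / log(2))
  expect_equal(log_mean(5, 5 * (1 + 1e-13)), 5, tolerance = 1e-12)
  expect_error(log_mean(0, 1), class = "perfusim_domain_error")
  expect_error(log_mean(2, -1), class = "perfusim_domain_error")
})

test_that("growth estimator equals the log-ratio closed form", {
  expect_equal(growth_rate_estimate(list(t = 0, X = 1e9), list(t = 1, X = 1e9)), 0)
  expect_equal(growth_rate_estimate(list(t = 0, X = 0.5e9), list(t = 1, X = 1e9)),
               log(2))
  expect_equal(growth_rate_estimate(list(t = 2, X = 1e9),
                                    list(t = 3, X = exp(1.35) * 1e9)),
               1.35, tolerance = 1e-12)
  expect_error(growth_rate_estimate(list(t = 1, X = 1e9), list(t = 1, X = 2e9)),
               class = "perfusim_ordering_error")

  set.seed(11)
  for (k in 1:50) {
    X1 <- 10^stats::runif(1, 6, 11); X2 <- X1 * 10^stats::runif(1, -3, 3)
    dt <- stats::runif(1, 0.1, 3)
    est <- growth_rate_estimate(list(t = 0, X = X1), list(t = dt, X = X2))
    expect_equal(est, log1p((X2 - X1) / X1) / dt, tolerance = 1e-12)
  }
})

test_that("batch metabolite estimators divide the slope by the log-mean density", {
  r <- function(t, X, glc = NA, lac = NA) list(t = t, X = X, glc = glc, lac = lac)
  expect_equal(substrate_rate_batch(r(0, 1e9, glc = 15), r(1, 1e9, glc = 15), "glc"), 0)
  expect_equal(substrate_rate_batch(r(0, 1e9, glc = 20), r(1, 1e9, glc = 10), "glc"), 1e-8)
  expect_equal(substrate_rate_batch(r(0, 1e9, glc = 10), r(1, 1e9, glc = 20), "glc"), -1e-8)
  expect_equal(waste_rate_batch(r(0, 1e9, lac = 0), r(1, 1e9, lac = 10), "lac"), 1e-8)
  expect_equal(waste_rate_batch(r(0, 2e9, lac = 5), r(0.5, 2e9, lac = 10), "lac"), 0.5e-8)
  expect_error(substrate_rate_batch(r(0, 1e9), r(1, 1e9, glc = 1), "glc"),
               class = "perfusim_missing_field")
})

test_that("perfusion estimators add the dilution term and check the regime", {
  feed <- medium_composition(glc = 20, gln = 5, osm = 340, label = "f")
  r <- function(t, X, glc = NA, lac = NA, F = 1, V = 1)
    list(t = t, X = X, glc = glc, lac = lac, F = F, V = V)
  # steady substrate: estimate reduces to (F/V)(S_f - S_bar)/X_bar
  expect_equal(substrate_rate_perfusion(r(0, 1e9, glc = 10), r(1, 1e9, glc = 10),
                                        "glc", feed), 1e-8)
  expect_equal(substrate_rate_perfusion(r(0, 1e9, glc = 20), r(1, 1e9, glc = 20),
                                        "glc", feed), 0)
  expect_equal(waste_rate_perfusion(r(0, 2e9, lac = 50, F = 2), r(1, 2e9, lac = 50, F = 2),
                                    "lac"), 5e-8)
  expect_error(substrate_rate_perfusion(r(0, 1e9, glc = 10, F = 0),
                                        r(1, 1e9, glc = 10, F = 0), "glc", feed),
               class = "perfusim_wrong_regime")
  # continuity: as F -> 0 the perfusion estimate approaches the batch one
  b <- waste_rate_batch(r(0, 1e9, lac = 5), r(1, 1e9, lac = 12), "lac")
  pf <- waste_rate_perfusion(r(0, 1e9, lac = 5, F = 1e-9), r(1, 1e9, lac = 12, F = 1e-9), "lac")
  expect_equal(pf, b, tolerance = 1e-8)
  feed0 <- medium_composition(glc = 8.5, gln = 5, osm = 340, label = "f0")
  bs <- substrate_rate_batch(r(0, 1e9, glc = 10), r(1, 1e9, glc = 8.5), "glc")
  ps <- substrate_rate_perfusion(r(0, 1e9, glc = 10, F = 1e-9),
                                 r(1, 1e9, glc = 8.5, F = 1e-9), "glc", feed0)
  expect_equal(ps, bs, tolerance = 1e-8)
})

test_that("estimate_rates dispatches regimes and flags log-mean degeneracies", {
  two <- tibble::tibble(t = 0:1, X = c(0.5e9, 1e9), glc = c(20, 10),
                        lac = c(1, 5), gln = c(2.5, 2), F = 0, V = 0.15)
  est <- estimate_rates(two)
  expect_equal(nrow(est), 1)
  expect_equal(est$regime, "batch")
  expect_equal(est$mu, log(2))

  obs <- synthesize_process(sampling_times = 0:7,
                            noise = noise_model(cv_X = 0, sd_met = 0,
                                                sd_osm = 0, sd_agg = 0))
  est8 <- estimate_rates(obs)
  expect_equal(nrow(est8), 7)
  expect_equal(est8$regime, c("batch", rep("perfusion", 6)))
  expect_true(all(is.na(est8$reason)))

  # perfused interval with zero waste at the opening sample
  degen <- tibble::tibble(t = 0:1, X = c(0.5e9, 1e9), glc = c(20, 10),
                          lac = c(0, 5), gln = c(2.5, 2), F = 0.15, V = 0.15)
  sch <- load_builtin("table3_schedule")
  estd <- estimate_rates(degen, feed_schedule = sch)
  expect_true(is.na(estd$q_lac))
  expect_match(estd$reason, "log-mean domain")
  expect_false(is.na(estd$q_glc))

  unsorted <- two[2:1, ]
  expect_error(estimate_rates(unsorted), class = "perfusim_ordering_error")
})

test_that("noise-free sampling recovers the simulator's own rates", {
  p <- kinetic_parameters()
  quiet <- noise_model(cv_X = 0, sd_met = 0, sd_osm = 0, sd_agg = 0)

  # growth-rate recovery is exact (log-ratio identity) at any cadence
  daily <- synthesize_process(p, sampling_times = 0:7, noise = quiet,
                              dt_out = 0.01)
  traj <- attr(daily, "trajectory")
  est <- estimate_rates(daily)
  for (i in seq_len(nrow(est))) {
    mu_true <- traj_interval_mean(traj, "mu_eff", est$t_start[i], est$t_end[i])
    expect_lt(abs(est$mu[i] - mu_true) / mu_true, 1e-3)
  }

  # daily metabolite estimates carry the documented log-mean interval bias;
  # it stays bounded by 25% on the reference process
  for (i in which(est$t_start >= 1 & est$t_end <= 5)) {
    g <- traj_interval_mean(traj, "mu_eff", est$t_start[i], est$t_end[i]) / p$mu_max
    expect_lt(abs(est$q_glc[i] - p$q_Glc_max * g) / (p$q_Glc_max * g), 0.25)
    expect_lt(abs(est$q_lac[i] - p$q_Lac_max * g) / (p$q_Lac_max * g), 0.25)
    expect_lt(abs(est$q_gln[i] - p$q_Gln_max * g) / (p$q_Gln_max * g), 0.25)
  }

  # the bias vanishes as the sampling cadence resolves the dynamics
  fine <- synthesize_process(p, sampling_times = seq(1, 5, by = 0.1),
                             noise = quiet, dt_out = 0.01)
  estf <- estimate_rates(fine)
  for (i in seq_len(nrow(estf))) {
    g <- traj_interval_mean(attr(fine, "trajectory"), "mu_eff",
                            estf$t_start[i], estf$t_end[i]) / p$mu_max
    expect_lt(abs(estf$q_glc[i] - p$q_Glc_max * g) / (p$q_Glc_max * g), 0.02)
    expect_lt(abs(estf$q_lac[i] - p$q_Lac_max * g) / (p$q_Lac_max * g), 0.02)
  }
})
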
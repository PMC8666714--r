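test_that("cell-free vessel relaxes to the feed by the washout closed form", {
  p <- kinetic_parameters()
  feed <- medium_composition(glc = 42.5, gln = 5, lac = 0, osm = 350,
                             label = "feed")
  init <- process_state(t = 0, X = 0, glc = 0, gln = 2, lac = 10, osm = 300,
                        d_agg = 0, V = 1)
  traj <- simulate_process(init, p, flat_schedule(7, feed, 1), t_end = 1,
                           dt_out = 0.05)
  for (v in c("glc", "gln", "lac", "osm")) {
    c0 <- init[[v]]
    cf <- feed[[switch(v, osm = "osm", v)]]
    closed <- cf + (c0 - cf) * exp(-7 * traj$t)
    scale <- max(abs(c0), abs(cf))
    expect_lt(max(abs(traj[[v]] - closed)) / scale, 1e-3)
  }
  expect_equal(tail(traj$glc, 1), 42.5 * (1 - exp(-7)), tolerance = 1e-3)
  expect_true(all(traj$X == 0))
})

test_that("with all factors saturating, growth is exponential at mu_max", {
  p <- saturated_parameters()
  feed <- medium_composition(glc = 1e9, gln = 1e9, osm = p$osm_ref, label = "x")
  traj <- simulate_process(saturated_state(p), p, flat_schedule(0, feed, 7),
                           t_end = 7, dt_out = 0.5)
  slope <- (log(traj$X) - log(traj$X[1])) / traj$t
  expect_lt(max(abs(slope[-1] - p$mu_max)) / p$mu_max, 1e-6)
})

test_that("aggregate diameter tracks the cube root of cell density", {
  traj <- simulate_reference()
  pick <- function(tt) which.min(abs(traj$t - tt))
  for (pair in list(c(1.5, 3), c(2, 6), c(4.5, 7))) {
    i <- pick(pair[1]); j <- pick(pair[2])
    ratio_d <- traj$d_agg[j] / traj$d_agg[i]
    ratio_X <- (traj$X[j] / traj$X[i])^(1 / 3)
    expect_equal(ratio_d, ratio_X, tolerance = 1e-6)
  }
})

test_that("state stays non-negative on the reference run and under stress", {
  traj <- simulate_reference()
  expect_true(all(traj$X >= 0))
  expect_true(all(traj$glc >= 0) && all(traj$gln >= 0) && all(traj$lac >= 0))

  # glutamine-poor feed forces near-exhaustion without going negative
  p <- kinetic_parameters()
  media <- load_builtin("media_e8")
  lean <- medium_composition(glc = 10, gln = 0.05, osm = 330, label = "lean")
  traj2 <- simulate_process(ref_initial(), p, flat_schedule(2, lean, 7),
                            t_end = 7, dt_out = 0.1)
  expect_true(all(traj2$gln >= 0) && all(traj2$glc >= 0))
})

test_that("feed switches are events: refining the grid leaves shared points", {
  coarse <- simulate_reference(dt_out = 0.5)
  fine <- simulate_reference(dt_out = 0.05)
  shared <- intersect(round(coarse$t, 9), round(fine$t, 9))
  i <- match(shared, round(coarse$t, 9)); j <- match(shared, round(fine$t, 9))
  expect_gt(length(shared), 10)
  expect_lt(max(abs(coarse$X[i] - fine$X[j]) / fine$X[j]), 1e-6)
  expect_lt(max(abs(coarse$lac[i] - fine$lac[j])) / max(fine$lac), 1e-6)
})

test_that("the reference process reproduces the expected day-7 endpoint", {
  traj <- simulate_reference()
  n <- nrow(traj)
  X7_per_mL <- traj$X[n] / 1000
  expect_lt(abs(X7_per_mL - 35e6) / 35e6, 0.10)
  expect_gte(traj$d_agg[n], 150)
  expect_lte(traj$d_agg[n], 350)
  expect_equal(traj$t[n], 7)
  expect_true(all(diff(traj$t) > 0))
  expect_true(all(traj$V == traj$V[1]))
})

test_that("invalid simulation setups are rejected", {
  p <- kinetic_parameters()
  sch <- load_builtin("table3_schedule")
  expect_error(simulate_process(ref_initial(), p, sch, t_end = 0),
               class = "perfusim_invalid_parameter")
  expect_error(simulate_process(ref_initial(), p, sch, t_end = 12),
               class = "perfusim_invalid_parameter")
  expect_error(feed_schedule(c(0, 2), c(1, 3), rate = c(1, 1),
                             medium = load_builtin("media_e8")$basis),
               class = "perfusim_invalid_parameter")
  expect_error(feed_schedule(1, 2, rate = 1,
                             medium = load_builtin("media_e8")$basis),
               class = "perfusim_invalid_parameter")
})
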
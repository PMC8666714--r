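test_that("constant-P/V speed translation matches hand evaluation", {
  expect_equal(scale_speed(80, 0.15, 0.034, 0.15, 0.034), 80)
  expect_equal(scale_speed(50, 0.1, 0.034, 0.8, 0.034), 100)   # 8x volume
  expect_equal(scale_speed(80, 0.15, 0.034, 0.5, 0.053),
               (80^3 * (0.5 / 0.15) * 0.034^5 / 0.053^5)^(1 / 3))
  expect_equal(round(scale_speed(80, 0.15, 0.034, 0.5, 0.053), 1), 57.0)
  expect_error(scale_speed(-80, 0.15, 0.034, 0.5, 0.053),
               class = "perfusim_domain_error")
})

test_that("specific power N^3 D^5 / V is invariant under scale_speed", {
  set.seed(7)
  for (k in 1:100) {
    N_i <- stats::runif(1, 10, 300)
    V_i <- stats::runif(1, 0.05, 2); V_o <- stats::runif(1, 0.05, 2)
    D_i <- stats::runif(1, 0.01, 0.2); D_o <- stats::runif(1, 0.01, 0.2)
    N_o <- scale_speed(N_i, V_i, D_i, V_o, D_o)
    pv_i <- N_i^3 * D_i^5 / V_i
    pv_o <- N_o^3 * D_o^5 / V_o
    expect_equal(pv_o, pv_i, tolerance = 1e-9)
  }
})

test_that("fitted volume-to-speed laws reproduce the printed setpoints", {
  expect_equal(speed_dasbox(0.15), 150.5 * 0.15^(1 / 3))
  expect_equal(round(speed_dasbox(0.15), 2), 79.97)
  expect_equal(round(speed_dasbox(0.15)), 80)
  expect_equal(round(speed_dasbox(0.25), 1), 94.8)
  expect_equal(speed_bioblock(1.0), 76.5)
  expect_equal(round(speed_bioblock(0.5), 2), 60.72)
  expect_equal(round(speed_bioblock(0.3), 1), 51.2)
  expect_warning(speed_dasbox(1.0))     # outside the DASbox range
  expect_equal(suppressWarnings(speed_dasbox(1.0)), 150.5)
  expect_error(speed_dasbox(0), class = "perfusim_domain_error")
})

test_that("within one system, scale_speed reduces to the cube-root volume law", {
  g <- load_builtin("dasbox")
  for (V in c(0.1, 0.2, 0.25)) {
    expect_equal(scale_speed(speed_dasbox(0.15), 0.15, g$impeller_diameter,
                             V, g$impeller_diameter),
                 speed_dasbox(V), tolerance = 1e-12)
  }
})

test_that("operating speed bounds scale with the cube root of volume", {
  g <- load_builtin("dasbox")
  expect_equal(speed_bounds(0.15, g), c(min = 50, max = 120))
  b <- speed_bounds(0.3, g)
  expect_equal(unname(b), c(50, 120) * 2^(1 / 3))
  expect_equal(round(unname(b), 1), c(63.0, 151.2))
  expect_error(speed_bounds(0.5, load_builtin("bioblock")),
               class = "perfusim_capability_error")
})

test_that("gassing and inoculum rules are exact arithmetic", {
  expect_equal(gassing_rate(0.15), 0.9)
  expect_equal(gassing_rate(1.0), 6.0)
  expect_equal(gassing_rate(0.5), 3.0)
  expect_error(gassing_rate(0), class = "perfusim_domain_error")
  expect_equal(inoculum_cells(0.15, 0.5e6), 75e6)
  expect_equal(inoculum_cells(1, 0), 0)
  expect_equal(inoculum_cells(0.5, 0.5e6), 250e6)
})

test_that("feed volumes match the bench worked examples and are additive", {
  sch <- load_builtin("table3_schedule")
  expect_equal(feed_volume(sch, 0.15, 1, 4), 0.825)
  expect_equal(feed_volume(sch, 0.15, 4, 7), 2.55)
  expect_equal(feed_volume(sch, 0.15, 3, 3), 0)
  # partial days pro-rated
  expect_equal(feed_volume(sch, 0.15, 1, 1.5), 0.15 * 1 * 0.5)
  set.seed(3)
  for (k in 1:20) {
    abc <- sort(stats::runif(3, 0, 7))
    expect_equal(feed_volume(sch, 0.15, abc[1], abc[2]) +
                 feed_volume(sch, 0.15, abc[2], abc[3]),
                 feed_volume(sch, 0.15, abc[1], abc[3]), tolerance = 1e-12)
  }
  expect_error(feed_volume(sch, 0.15, 4, 1), class = "perfusim_ordering_error")
  expect_error(feed_volume(sch, 0.15, 1, 9), class = "perfusim_domain_error")
})

test_that("plan_process assembles the planning table", {
  pl <- plan_process(0.15)
  expect_equal(pl$summary$inoculum_cells, 75e6)
  expect_equal(round(pl$summary$speed_rpm), 80)
  expect_equal(pl$summary$gassing_sL_h, 0.9)
  expect_equal(sum(pl$feed$volume_L[pl$feed$start_day >= 1 &
                                    pl$feed$end_day <= 4]), 0.825)
  expect_equal(nrow(pl$feed), 7)
})
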
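test_that("the ending potential follows the printed linear rule for all option sets", {
  # endpoints of the three (h31, h32) sets at the reference rates 1 and 5 mm/day
  expect_identical(h3_of_tp(1, ihth = 1), -11)
  expect_identical(h3_of_tp(5, ihth = 1), -5)
  expect_identical(h3_of_tp(1, ihth = 2), -14)
  expect_identical(h3_of_tp(5, ihth = 2), -8)
  expect_identical(h3_of_tp(1, ihth = 3), -16)
  expect_identical(h3_of_tp(5, ihth = 3), -10)
  # linear midpoint and clamping outside [Tp1, Tp2]
  expect_equal(h3_of_tp(3, ihth = 1), -8)
  expect_identical(h3_of_tp(0.2, ihth = 1), -11)
  expect_identical(h3_of_tp(9, ihth = 1), -5)
  expect_error(h3_options(4), class = "rootflow_domain_error")
  # linearity across the interior for every set
  for (s in 1:3) {
    tp <- seq(1, 5, by = 0.5)
    h3 <- h3_of_tp(tp, ihth = s)
    expect_equal(diff(h3), rep(diff(h3)[1], length(tp) - 1))
  }
})

test_that("the stress trapezoid has the right plateau, limbs and zeros", {
  h1 <- -0.1; h2 <- -0.25; h3 <- -8; h4 <- -150
  a <- function(h) stress_alpha(h, h1, h2, h3, h4)
  expect_identical(a((h2 + h3) / 2), 1)
  expect_identical(a(h2), 1)
  expect_identical(a(h3), 1)
  expect_identical(a(h1), 0)
  expect_identical(a(h4), 0)
  expect_identical(a(0), 0)
  expect_identical(a(-1000), 0)
  expect_equal(a((h3 + h4) / 2), 0.5)
  expect_equal(a((h1 + h2) / 2), 0.5)
  # continuity and range on a fine grid
  h <- seq(-200, 0, by = 0.01)
  v <- a(h)
  expect_true(all(v >= 0 & v <= 1))
  # steepest limb is the rise over h1 - h2 = 0.15 m: slope 1/0.15
  expect_lt(max(abs(diff(v))), 0.07)
})

test_that("root depth grows linearly between thaw and maturity", {
  cfg <- uptake_config(zr_max = 1.2, jthaw = 110, jmatur = 190, l0 = 0.05)
  expect_identical(root_depth(110, cfg), 0.05)
  expect_identical(root_depth(50, cfg), 0.05)
  expect_identical(root_depth(190, cfg), 1.2)
  expect_identical(root_depth(250, cfg), 1.2)
  expect_equal(root_depth(150, cfg), (0.05 + 1.2) / 2)
})

test_that("the power-law sink integrates to Tp and vanishes below the roots", {
  grid <- flow_grid(100, 0.01)
  cfg <- wet_cfg(beta = 2, zr_max = 1)
  h <- rep(-1, 100)   # on the optimal plateau -> alpha = 1
  sk <- sink_prasad(h, grid, Tp = 5, L = 1, cfg)
  expect_equal(sk$actual_transpiration, 5, tolerance = 0.01)
  expect_true(all(sk$S >= 0))
  # Tp = 0 gives an all-zero profile
  expect_identical(sink_prasad(h, grid, 0, 1, cfg)$S, rep(0, 100))
  # beta -> 0 limit: uniform density 1/L
  cfg0 <- wet_cfg(beta = 1e-12, zr_max = 1)
  sk0 <- sink_prasad(h, grid, 5, 1, cfg0)
  expect_equal(max(sk0$S), min(sk0$S[sk0$S > 0]), tolerance = 1e-6)
  # no uptake below the rooting depth
  skL <- sink_prasad(h, grid, 5, 0.5, cfg)
  expect_true(all(skL$S[grid$z > 0.5] == 0))
  expect_error(sink_prasad(h, grid, 5, 0, cfg),
               class = "rootflow_domain_error")
})

test_that("the discrete power-law density converges to 1 under refinement", {
  cfg <- wet_cfg(beta = 2, zr_max = 1)
  total <- function(nz) {
    grid <- flow_grid(nz, 1 / nz)
    sink_prasad(rep(-1, nz), grid, Tp = 1, L = 1, cfg)$actual_transpiration
  }
  expect_lt(abs(total(20) - 1), 0.01)     # dz = L/20: within 1%
  expect_lt(abs(total(200) - 1), 1e-4)    # dz = L/200: within 0.01%
})

test_that("the cubic root density matches hand-evaluated values and floors at 0", {
  expect_identical(lnrd_wu(0), 2.21)
  expect_equal(lnrd_wu(1), 2.21 - 3.72 + 3.46 - 1.87)
  expect_equal(lnrd_wu(0.5), 0.98125)
  # default coefficients stay positive on [0, 1]
  expect_true(all(lnrd_wu(seq(0, 1, by = 0.001)) > 0))
  # user coefficients dipping negative are floored
  expect_identical(lnrd_wu(1, c(0.1, -2, 0, 0)), 0)
  expect_error(lnrd_wu(1.5), class = "rootflow_domain_error")
})

test_that("the uncompensated cubic-density sink scales linearly with stress", {
  grid <- flow_grid(40, 0.025)
  cfg <- wet_cfg(icps = 3, zr_max = 1)
  h <- rep(-1, 40)
  sk <- sink_wu(h, grid, Tp = 4, Zr = 1, cfg)
  expect_equal(sk$actual_transpiration, 4, tolerance = 1e-12)
  # uniform alpha = 0.5: put heads on the falling limb midpoint
  h3 <- h3_of_tp(4, ihth = 1)
  h_half <- (h3 + cfg$h4) / 2
  sk2 <- sink_wu(rep(h_half, 40), grid, 4, 1, cfg)
  expect_equal(sk2$actual_transpiration, 2, tolerance = 1e-12)
  # stressed top, wet bottom: total < Tp, no redistribution
  h_mix <- c(rep(-1000, 20), rep(-1, 20))
  sk3 <- sink_wu(h_mix, grid, 4, 1, cfg)
  expect_true(all(sk3$S[1:20] == 0))
  expect_lt(sk3$actual_transpiration, 4)
  ref <- sink_wu(rep(-1, 40), grid, 4, 1, cfg)
  expect_equal(sk3$S[21:40], ref$S[21:40])   # wet blocks unchanged
})

test_that("the compensated sink honors the algebraic uptake identities", {
  grid <- flow_grid(40, 0.025)
  cfg <- wet_cfg(icps = 2, zr_max = 1, lambda = 0.8)
  # all alpha = 1 -> total = Tp
  sk <- sink_li_yadav(rep(-1, 40), grid, Tp = 3, Zr = 1, cfg)
  expect_equal(sk$actual_transpiration, 3, tolerance = 1e-12)
  # uniform alpha = a -> total = a * Tp
  h3 <- h3_of_tp(3, ihth = 1)
  h_a <- h3 + 0.25 * (cfg$h4 - h3)   # alpha = 0.75
  sk2 <- sink_li_yadav(rep(h_a, 40), grid, 3, 1, cfg)
  expect_equal(sk2$actual_transpiration, 0.75 * 3, tolerance = 1e-10)
  # binary alpha -> total = Tp, uptake shifted entirely to wet blocks
  h_bin <- c(rep(-1000, 20), rep(-1, 20))
  sk3 <- sink_li_yadav(h_bin, grid, 3, 1, cfg)
  expect_equal(sk3$actual_transpiration, 3, tolerance = 1e-12)
  expect_true(all(sk3$S[1:20] == 0))
  # full stress: zero profile flagged, not an error
  sk4 <- sink_li_yadav(rep(-1000, 40), grid, 3, 1, cfg)
  expect_identical(sk4$S, rep(0, 40))
  expect_true(attr(sk4, "full_stress"))
})

test_that("compensated totals match the direct-summation oracle on random stress", {
  set.seed(77)
  grid <- flow_grid(30, 1 / 30)
  cfg <- wet_cfg(icps = 2, zr_max = 1, lambda = 1.3)
  lnrd <- lnrd_wu(grid$z / 1, cfg$r_coeffs)
  h3 <- h3_of_tp(2, ihth = 1)
  for (k in 1:25) {
    a_target <- runif(30, 0.05, 1)
    h <- cfg$h4 + a_target * (h3 - cfg$h4)   # falling limb: alpha = a_target
    sk <- sink_li_yadav(h, grid, Tp = 2, Zr = 1, cfg)
    oracle <- 2 * sum(a_target^2 * lnrd^cfg$lambda) /
      sum(a_target * lnrd^cfg$lambda)
    expect_equal(sk$actual_transpiration, oracle, tolerance = 1e-9)
    expect_gte(oracle / 2 + 1e-12, min(a_target))
    expect_lte(oracle / 2 - 1e-12, max(a_target))
  }
})

test_that("compensated total uptake is monotone in any single block's stress", {
  grid <- flow_grid(20, 0.05)
  cfg <- wet_cfg(icps = 2, zr_max = 1, lambda = 1)
  h3 <- h3_of_tp(2, ihth = 1)
  set.seed(13)
  a <- runif(20, 0.1, 0.9)
  h <- cfg$h4 + a * (h3 - cfg$h4)
  base <- sink_li_yadav(h, grid, 2, 1, cfg)$actual_transpiration
  for (i in c(1, 7, 20)) {
    h2 <- h
    h2[i] <- cfg$h4 + min(1, a[i] + 0.05) * (h3 - cfg$h4)
    expect_gte(sink_li_yadav(h2, grid, 2, 1, cfg)$actual_transpiration,
               base - 1e-12)
  }
})

test_that("compute_sink dispatches on the model selector and refreshes h3", {
  grid <- flow_grid(20, 0.05)
  h <- rep(-7, 20)   # between h3(Tp=1) = -11 and h3(Tp=5) = -5
  day <- 200         # past maturity -> full root depth
  cfg1 <- wet_cfg(icps = 1, beta = 2, zr_max = 1, jmatur = 190)
  expect_equal(compute_sink(h, grid, 2, day, cfg1)$S,
               sink_prasad(h, grid, 2, root_depth(day, cfg1), cfg1)$S)
  # at Tp = 1, h3 = -11 < -7 -> optimal; at Tp = 5, h3 = -5 > -7 -> stressed
  full <- compute_sink(h, grid, 1, day, cfg1)
  expect_equal(full$actual_transpiration, 1, tolerance = 0.01)
  stressed <- compute_sink(h, grid, 5, day, cfg1)
  a_exp <- (-7 - cfg1$h4) / (h3_of_tp(5, 1) - cfg1$h4)
  expect_equal(stressed$actual_transpiration, 5 * a_exp, tolerance = 0.01)
  expect_lt(stressed$actual_transpiration / 5, 1 - 1e-3)
  # zero demand -> zero profile for every model
  for (icps in 1:3) {
    cfg <- wet_cfg(icps = icps, zr_max = 1)
    expect_identical(compute_sink(h, grid, 0, day, cfg)$S, rep(0, 20))
  }
  # compensation keeps Tp in uniformly wet soil for any admissible lambda
  for (lam in c(0.01, 1, 2)) {
    cfg <- wet_cfg(icps = 2, zr_max = 1, lambda = lam)
    expect_equal(compute_sink(rep(-1, 20), grid, 3, day,
                              cfg)$actual_transpiration, 3,
                 tolerance = 1e-10)
  }
  # distributions differ across lambda even when totals agree
  s_a <- compute_sink(rep(-1, 20), grid, 3, day,
                      wet_cfg(icps = 2, zr_max = 1, lambda = 0.01))$S
  s_b <- compute_sink(rep(-1, 20), grid, 3, day,
                      wet_cfg(icps = 2, zr_max = 1, lambda = 2))$S
  expect_gt(max(abs(s_a - s_b)), 0)
})

test_that("configuration validation enforces the documented parameter ranges", {
  expect_error(uptake_config(lambda = 0.005), class = "rootflow_domain_error")
  expect_error(uptake_config(lambda = 2.5), class = "rootflow_domain_error")
  expect_no_error(uptake_config(lambda = 0.01))
  expect_no_error(uptake_config(lambda = 2.0))
  expect_error(uptake_config(icps = 4), class = "rootflow_domain_error")
  expect_error(uptake_config(ihth = 0), class = "rootflow_domain_error")
  expect_error(uptake_config(beta = -1), class = "rootflow_domain_error")
  expect_error(uptake_config(jthaw = 200, jmatur = 150),
               class = "rootflow_domain_error")
  expect_error(uptake_config(l0 = 0), class = "rootflow_domain_error")
})
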
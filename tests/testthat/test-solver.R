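test_that("thomas_solve matches hand solves and the identity system", {
  # identity: A = C = 0, B = 1 -> x = D
  d <- c(3, -1, 2, 0.5)
  expect_equal(thomas_solve(list(A = rep(0, 4), B = rep(1, 4),
                                 C = rep(0, 4), D = d)), d)
  # 3x3 hand solve: B=(2,2,2), A=(0,-1,-1), C=(-1,-1,0), D=(1,0,1)
  expect_equal(thomas_solve(list(A = c(0, -1, -1), B = c(2, 2, 2),
                                 C = c(-1, -1, 0), D = c(1, 0, 1))),
               c(1, 1, 1))
})

test_that("thomas_solve agrees with a dense solve on 50 random systems", {
  set.seed(101)
  worst <- 0
  for (k in 1:50) {
    sys <- rand_tridiag(sample(3:40, 1))
    worst <- max(worst, max(abs(thomas_solve(sys) - dense_solve(sys))))
  }
  expect_lt(worst, 1e-10)
})

test_that("thomas_solve rejects malformed or singular systems", {
  expect_error(thomas_solve(list(A = c(1, 0), B = c(1, 1), C = c(0, 0),
                                 D = c(1, 1))),
               class = "rootflow_domain_error")
  expect_error(thomas_solve(list(A = c(0, 0), B = c(0, 1), C = c(0, 0),
                                 D = c(1, 1))),
               class = "rootflow_domain_error")
})

test_that("internode conductivity stays between its inputs", {
  expect_equal(internode_K(2e-6, 2e-6), 2e-6)
  expect_equal(internode_K(1e-6, 4e-6), 2.5e-6)
  expect_equal(internode_K(0, 1e-6, "geometric"), 0)
  expect_equal(internode_K(1e-6, 4e-6, "geometric"), 2e-6)
})

test_that("assembly: gravity terms cancel for uniform state, sink only shifts D", {
  col <- small_column()
  st <- flow_state(0, rep(-2, col$grid$nz), models = col$models)
  bc <- boundary_condition("flux", 0)
  dt <- 60
  s0 <- assemble_system(st, col$grid, col$models, bc,
                        rep(0, col$grid$nz), dt)
  cv <- water_capacity(col$models[[1]], -2)
  i <- 2:(col$grid$nz - 1)
  expect_equal(s0$D[i], rep(cv * -2 / dt, length(i)))
  expect_equal(s0$A[1], 0)
  expect_equal(s0$C[col$grid$nz], 0)
  expect_true(all(s0$B > 0))
  sink <- runif(col$grid$nz, 0, 1e-8)
  s1 <- assemble_system(st, col$grid, col$models, bc, sink, dt)
  expect_identical(s1$A, s0$A)
  expect_identical(s1$B, s0$B)
  expect_identical(s1$C, s0$C)
  expect_equal(s1$D, s0$D - sink)
})

test_that("assembled system solves like a dense solve of the same matrix", {
  set.seed(5)
  col <- small_column()
  st <- flow_state(0, -exp(runif(col$grid$nz, log(0.1), log(20))),
                   models = col$models)
  sys <- assemble_system(st, col$grid, col$models,
                         boundary_condition("flux", 1e-8),
                         runif(col$grid$nz, 0, 1e-8), 60)
  expect_lt(max(abs(thomas_solve(sys) - dense_solve(sys))), 1e-10)
})

test_that("interface fluxes: hydrostatic none, uniform head pure gravity", {
  col <- small_column()
  K_half <- rep(3e-8, col$grid$nz + 1)
  bc <- boundary_condition("flux", 0)
  J <- interface_fluxes(hydrostatic_h(col$grid, -10), col$grid, K_half, bc)
  expect_equal(J[2:col$grid$nz], rep(0, col$grid$nz - 1))
  expect_equal(J[col$grid$nz + 1], 3e-8)   # unit-gradient bottom: J = K
  J2 <- interface_fluxes(rep(-3, col$grid$nz), col$grid, K_half, bc)
  expect_equal(J2[2:col$grid$nz], rep(3e-8, col$grid$nz - 1))
})

test_that("mass-balance update telescopes exactly and fixes trivial cases", {
  col <- small_column()
  nz <- col$grid$nz
  th <- runif(nz, 0.2, 0.4)
  # zero flux, zero sink and uniform flux leave theta unchanged
  expect_identical(mass_balance_update(th, rep(0, nz + 1), rep(0, nz),
                                       60, col$grid), th)
  expect_equal(mass_balance_update(th, rep(2e-7, nz + 1), rep(0, nz),
                                   60, col$grid), th)
  # telescoping storage identity
  set.seed(3)
  J <- runif(nz + 1, -1e-7, 1e-7)
  S <- runif(nz, 0, 1e-8)
  dt <- 120
  th2 <- mass_balance_update(th, J, S, dt, col$grid)
  expect_equal(sum(th2 - th) * col$grid$dz,
               dt * (J[1] - J[nz + 1]) - dt * sum(S) * col$grid$dz)
  # single block, hand arithmetic
  g1 <- flow_grid(3, 0.5)
  r <- mass_balance_update(c(0.3, 0.3, 0.3), c(1e-7, 2e-7, 0, 0),
                           c(1e-8, 0, 0), 100, g1)
  expect_equal(r[1], 0.3 - 100 * (2e-7 - 1e-7) / 0.5 - 100 * 1e-8)
})

test_that("a dry hydrostatic column is a fixed point of the flux-update step", {
  col <- small_column()
  h0 <- hydrostatic_h(col$grid, -100)
  st <- flow_state(0, h0, models = col$models)
  new <- flux_update_step(st, col$grid, col$models,
                          boundary_condition("flux", 0),
                          rep(0, col$grid$nz), 60)
  expect_lt(max(abs(new$h - h0)), 1e-8)
  expect_lt(max(abs(new$theta - st$theta)), 1e-12)
})

test_that("gentle flux on an unsaturated column keeps h-theta retention-consistent", {
  col <- small_column()
  st <- flow_state(0, rep(-5, col$grid$nz), models = col$models)
  new <- flux_update_step(st, col$grid, col$models,
                          boundary_condition("flux", 5e-9),
                          rep(0, col$grid$nz), 300)
  th_from_h <- vapply(seq_len(col$grid$nz),
                      function(i) theta_of_h(col$models[[i]], new$h[i]),
                      numeric(1))
  expect_equal(new$theta, th_from_h, tolerance = 1e-10)
  expect_true(all(new$theta < 0.45))
})

test_that("sustained flux above K_s saturates the surface without exceeding theta_s", {
  col <- small_column(nz = 10, dz = 0.05)
  st <- flow_state(0, rep(-0.3, col$grid$nz), models = col$models)
  bc <- boundary_condition("flux", 5e-6)   # 5x K_s
  saturated_seen <- FALSE
  for (k in 1:200) {
    st <- flux_update_step(st, col$grid, col$models, bc,
                           rep(0, col$grid$nz), 60)
    if (st$theta[1] >= 0.45 - 1e-6) saturated_seen <- TRUE
  }
  expect_true(saturated_seen)
  expect_true(all(st$theta <= 0.45 + 1e-12))
})

test_that("the R and compiled engines produce the same trajectories", {
  sp <- scenario_spec(days = 2, nz = 12, dz = 0.1, seed = 19,
                      rain_mean_interval = 2, rain_mean_depth = 10)
  sc <- make_scenario(sp)
  args <- list(sc$profile, sc$grid, sc$init_theta, sc$weather, sc$uptake)
  r_cpp <- do.call(run_simulation,
                   c(args, list(control = run_control(dt = 600,
                                                      engine = "cpp"))))
  r_r <- do.call(run_simulation,
                 c(args, list(control = run_control(dt = 600,
                                                    engine = "r"))))
  expect_equal(r_cpp$theta, r_r$theta, tolerance = 1e-12)
  expect_equal(r_cpp$h, r_r$h, tolerance = 1e-10)
  expect_equal(r_cpp$ledger, r_r$ledger, tolerance = 1e-10)
})

test_that("a static scenario accumulates nothing and stays static", {
  col <- small_column(nz = 8, dz = 0.1)
  wx <- data.frame(day = 1:2, et0 = 0, tair = 10, rain = 0, rh = 0.5,
                   lai = 0)
  h0 <- hydrostatic_h(col$grid, -100)
  th0 <- theta_of_h(col$models[[1]], h0)
  cfg <- uptake_config(zr_max = 0.5, jthaw = 100, jmatur = 150)
  run <- run_simulation(col$profile, col$grid, th0, wx, cfg,
                        run_control(dt = 3600))
  expect_equal(run$ledger$C_AEVA, 0)
  expect_equal(run$ledger$C_ATRA, 0)
  expect_lt(abs(run$ledger$WBELOW), 1e-6)
  expect_lt(max(abs(run$theta[2, ] - th0)), 1e-9)
})

test_that("rain-only infiltration below K_s is fully recovered (conservation audit)", {
  col <- small_column(nz = 20, dz = 0.05)
  wx <- data.frame(day = 1:5, et0 = 0, tair = 10,
                   rain = c(10, 0, 20, 0, 5), rh = 0.5, lai = 0)
  th0 <- rep(theta_of_h(col$models[[1]], -2), col$grid$nz)
  cfg <- uptake_config(zr_max = 0.5, jthaw = 100, jmatur = 150)
  run <- run_simulation(col$profile, col$grid, th0, wx, cfg,
                        run_control(dt = 120))
  expect_equal(run$ledger$BIGI, 35, tolerance = 1e-6)
  expect_lt(abs(run$ledger$PCTDIF), 1e-4)
})

test_that("halving dz and dt changes cumulative infiltration by under 2 percent", {
  base <- make_scenario(scenario_spec(days = 15, nz = 20, dz = 0.1,
                                      seed = 23, rain_mean_interval = 4,
                                      rain_mean_depth = 12))
  fine <- make_scenario(scenario_spec(days = 15, nz = 40, dz = 0.05,
                                      seed = 23, rain_mean_interval = 4,
                                      rain_mean_depth = 12))
  cfg <- base$uptake
  r1 <- run_simulation(base$profile, base$grid, base$init_theta,
                       base$weather, cfg, run_control(dt = 240))
  cfg2 <- fine$uptake; cfg2$l0 <- cfg$l0   # same seed depth across grids
  r2 <- run_simulation(fine$profile, fine$grid, fine$init_theta,
                       fine$weather, cfg2, run_control(dt = 120))
  inf1 <- sum(r1$daily$inf_mm)
  inf2 <- sum(r2$daily$inf_mm)
  expect_lt(abs(inf1 - inf2) / abs(inf2), 0.02)
})
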
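#' Numerical controls for a simulation run
#'
#' @param dt base time step (s, default 60); halved automatically (and
#'   recovered) when a step produces out-of-bounds or non-finite state
#' @param k_ext canopy extinction coefficient for the ET partition
#' @param h_dry air-dry surface head limiting evaporation (m)
#' @param kmean internode conductivity averaging, "arithmetic" or
#'   "geometric"
#' @param sat_tol saturation tolerance for the trial-acceptance test
#' @param engine "cpp" (compiled day loop, default) or "r" (pure-R
#'   reference loop built from the per-operation functions)
#' @return a list of class `run_control`
#' @export
run_control <- function(dt = 60, k_ext = 0.5, h_dry = -1000,
                        kmean = c("arithmetic", "geometric"),
                        sat_tol = 1e-9, engine = c("cpp", "r")) {
  kmean <- match.arg(kmean)
  engine <- match.arg(engine)
  if (dt <= 0 || dt > 86400) stop_domain("need 0 < dt <= 86400 s")
  if (h_dry >= 0) stop_domain("h_dry must be negative")
  structure(list(dt = dt, k_ext = k_ext, h_dry = h_dry, kmean = kmean,
                 sat_tol = sat_tol, engine = engine),
            class = "run_control")
}

#' Run the soil water flow simulation
#'
#' Advances the profile through the weather series in sub-daily steps:
#' daily forcing is partitioned into potential evaporation and
#' transpiration ([partition_et()]), evaporation is limited each step by
#' the surface exfiltration capacity, the net surface flux feeds the flux
#' upper boundary, the sink profile is evaluated from old-time heads
#' ([compute_sink()]), and each step applies the trial/accept flux-update
#' scheme.  Daily per-block h and theta are recorded and a water-balance
#' ledger is accumulated.
#'
#' Ledger conventions: WADD is the rain applied over the run (mm); BIGI is
#' the gross infiltration recovered from the simulation (storage change +
#' drainage + transpiration + evaporation, mm), so the closure error
#' PCTDIF = (BIGI - WADD)/WADD * 100 is near zero when mass is conserved;
#' WBELOW is drainage through the bottom boundary, C_AEVA and C_ATRA the
#' cumulative actual evaporation and transpiration.
#'
#' @param profile a [soil_profile()]
#' @param grid a [flow_grid()]
#' @param init_theta initial per-block water content (length nz)
#' @param weather weather data.frame (day, et0, tair, rain, rh, lai)
#' @param uptake an [uptake_config()]
#' @param control a [run_control()]
#' @return an object of class `als_run`: daily `h` and `theta` matrices
#'   (days x nz), a `daily` data.frame of water-balance components, the
#'   `ledger` (BIGI, WADD, WBELOW, C_AEVA, C_ATRA, PCTDIF, all mm or %),
#'   and the final state
#' @export
run_simulation <- function(profile, grid, init_theta, weather, uptake,
                           control = run_control()) {
  if (!inherits(uptake, "uptake_config"))
    stop_domain("uptake must be an uptake_config")
  if (!inherits(control, "run_control"))
    stop_domain("control must be a run_control")
  validate_weather(weather)
  models <- block_models(profile, grid)
  if (length(init_theta) != grid$nz)
    stop_domain("init_theta length %d != nz = %d",
                length(init_theta), grid$nz)
  for (i in seq_len(grid$nz))
    if (init_theta[i] <= models[[i]]$theta_r ||
        init_theta[i] > models[[i]]$theta_s + 1e-12)
      stop_domain("initial theta %g out of range in block %d",
                  init_theta[i], i)
  if (uptake$zr_max > grid$z_max + 1e-9)
    stop_domain("zr_max (%g m) exceeds profile depth (%g m)",
                uptake$zr_max, grid$z_max)

  h0 <- vapply(seq_len(grid$nz),
               function(i) h_of_theta(models[[i]],
                                      min(init_theta[i],
                                          models[[i]]$theta_s)),
               numeric(1))
  part <- partition_et(weather$et0, weather$lai, control$k_ext)

  core <- if (control$engine == "cpp") {
    lay <- block_layer_index(profile, grid)
    run_core(grid$nz, grid$dz, as.integer(lay),
             lapply(profile$models, as_layer_list), h0,
             as.numeric(weather$day), as.numeric(weather$rain),
             part$Ep, part$Tp,
             list(icps = uptake$icps, beta = uptake$beta,
                  zr_max = uptake$zr_max, lambda = uptake$lambda,
                  jthaw = uptake$jthaw, jmatur = uptake$jmatur,
                  l0 = uptake$l0, r_coeffs = uptake$r_coeffs,
                  h1 = uptake$h1, h2 = uptake$h2, h4 = uptake$h4,
                  h31 = uptake$h31, h32 = uptake$h32,
                  tp1 = uptake$tp1, tp2 = uptake$tp2),
             control$dt, control$h_dry,
             if (control$kmean == "geometric") 2L else 1L,
             control$sat_tol)
  } else {
    .run_r_engine(grid, models, h0, weather, part, uptake, control)
  }

  storage <- rowSums(core$theta) * grid$dz * 1000
  storage0 <- sum(vapply(seq_len(grid$nz),
                         function(i) theta_of_h(models[[i]], h0[i]),
                         numeric(1))) * grid$dz * 1000
  daily <- data.frame(day = weather$day, rain = weather$rain,
                      et0 = weather$et0, Ep = part$Ep, Tp = part$Tp,
                      inf_mm = core$inf_mm, evap_mm = core$evap_mm,
                      tran_mm = core$tran_mm, drain_mm = core$drain_mm,
                      storage_mm = storage)
  wadd <- sum(weather$rain)
  wbelow <- sum(core$drain_mm)
  c_aeva <- sum(core$evap_mm)
  c_atra <- sum(core$tran_mm)
  bigi <- (storage[length(storage)] - storage0) + wbelow + c_atra + c_aeva
  pctdif <- if (wadd > 0) (bigi - wadd) / wadd * 100 else NA_real_
  structure(list(
    days = weather$day, h = core$h, theta = core$theta, daily = daily,
    ledger = list(BIGI = bigi, WADD = wadd, WBELOW = wbelow,
                  C_AEVA = c_aeva, C_ATRA = c_atra, PCTDIF = pctdif),
    final = flow_state(t = nrow(daily) * 86400, h = core$h_final,
                       theta = core$theta_final),
    grid = grid, profile = profile, uptake = uptake, control = control),
    class = "als_run")
}

#' @export
print.als_run <- function(x, ...) {
  lg <- x$ledger
  cat(sprintf("<als_run: %d days, nz = %d, dz = %g m>\n",
              length(x$days), x$grid$nz, x$grid$dz))
  cat(sprintf("  WADD  %8.2f mm rain applied\n", lg$WADD))
  cat(sprintf("  BIGI  %8.2f mm gross infiltration recovered\n", lg$BIGI))
  cat(sprintf("  C_AEVA %7.2f mm evaporation   C_ATRA %7.2f mm transpiration\n",
              lg$C_AEVA, lg$C_ATRA))
  cat(sprintf("  WBELOW %7.2f mm deep drainage\n", lg$WBELOW))
  cat(sprintf("  PCTDIF %7.4f %% water-balance closure error\n",
              if (is.na(lg$PCTDIF)) NA else lg$PCTDIF))
  invisible(x)
}

# Pure-R day loop mirroring the compiled engine step for step; used as the
# reference implementation in tests and for small runs.
.run_r_engine <- function(grid, models, h0, weather, part, uptake,
                          control) {
  nz <- grid$nz
  ndays <- nrow(weather)
  st <- flow_state(0, h0, models = models)
  out_h <- out_th <- matrix(NA_real_, ndays, nz)
  inf <- drain <- eva <- tra <- numeric(ndays)
  for (d in seq_len(ndays)) {
    Tp <- part$Tp[d]; Ep <- part$Ep[d]; rain <- weather$rain[d]
    remaining <- 86400
    dt <- control$dt
    while (remaining > 1e-9) {
      dt_use <- min(dt, remaining)
      actE <- evaporation_limit(Ep, st$h[1], models[[1]], grid$dz,
                                control$h_dry)
      J0 <- surface_flux(rain, actE)
      sk <- compute_sink(st$h, grid, Tp, weather$day[d], uptake)
      bc <- boundary_condition("flux", J0)
      new_st <- tryCatch(
        flux_update_step(st, grid, models, bc, sk$S, dt_use,
                         kmean = control$kmean,
                         sat_tol = control$sat_tol),
        rootflow_step_error = function(e) NULL)
      if (is.null(new_st)) {
        dt <- dt / 2
        if (dt < control$dt / 4096)
          stop_step("time step collapsed below dt/4096 on day %g",
                    weather$day[d])
        next
      }
      J <- attr(new_st, "fluxes")
      inf[d] <- inf[d] + J0 * dt_use * 1000
      drain[d] <- drain[d] + J[nz + 1] * dt_use * 1000
      tra[d] <- tra[d] + sum(sk$S * grid$dz) * dt_use * 1000
      eva[d] <- eva[d] + actE * dt_use / 86400
      st <- new_st
      remaining <- remaining - dt_use
      if (dt < control$dt) dt <- min(dt * 2, control$dt)
    }
    out_h[d, ] <- st$h
    out_th[d, ] <- st$theta
  }
  list(h = out_h, theta = out_th, inf_mm = inf, drain_mm = drain,
       evap_mm = eva, tran_mm = tra, h_final = st$h,
       theta_final = st$theta)
}
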
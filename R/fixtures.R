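#' Synthetic scenario specification
#'
#' Deterministic (seeded) generator of a complete, self-contained test
#' scenario: a loam-like van Genuchten soil, a growing-season weather
#' series with seeded rain pulses and a seasonal ET curve, an initial
#' water-content profile, the true root parameters, and an observation
#' plan.  The soil constants are fixture conventions, not field data.
#'
#' @param days simulation length in days (default 111, a May 14 - Sep 1
#'   window; day numbers start at Julian day `start_day`)
#' @param start_day first Julian day (default 134)
#' @param nz,dz grid blocks and thickness (default 40 x 0.05 m = 2 m)
#' @param beta,zr_max true root parameters of the scenario
#' @param icps uptake model used for the truth run
#' @param jthaw,jmatur growth calendar (Julian days)
#' @param et0_base,et0_amp seasonal potential ET (mm/day): base plus a
#'   half-sine over the window
#' @param rain_mean_interval mean days between rain pulses
#' @param rain_mean_depth mean rain pulse depth (mm)
#' @param lai_max peak leaf area index reached at jmatur
#' @param h_init initial uniform pressure head (m)
#' @param obs_days observation days (Julian); the default is every day of
#'   the window, emulating logging soil-moisture sensors scored throughout
#'   the simulation period
#' @param obs_depths observation depths (m)
#' @param noise_sd multiplicative observation noise sd (0 = noiseless)
#' @param seed RNG seed making the scenario reproducible
#' @return a list of class `scenario_spec`
#' @export
scenario_spec <- function(days = 111, start_day = 134, nz = 40, dz = 0.05,
                          beta = 2.0, zr_max = 1.0, icps = 1,
                          jthaw = 110, jmatur = 190,
                          et0_base = 2.0, et0_amp = 3.0,
                          rain_mean_interval = 9, rain_mean_depth = 14,
                          lai_max = 2.5, h_init = -0.5,
                          obs_days = NULL, obs_depths = NULL,
                          noise_sd = 0, seed = 42) {
  if (days < 1) stop_domain("need days >= 1")
  if (is.null(obs_days))
    obs_days <- seq(start_day, start_day + days - 1)
  if (is.null(obs_depths))
    obs_depths <- seq(0.075, min(1.575, nz * dz - dz / 2), by = 0.2)
  structure(list(days = days, start_day = start_day, nz = nz, dz = dz,
                 beta = beta, zr_max = zr_max, icps = icps,
                 jthaw = jthaw, jmatur = jmatur,
                 et0_base = et0_base, et0_amp = et0_amp,
                 rain_mean_interval = rain_mean_interval,
                 rain_mean_depth = rain_mean_depth,
                 lai_max = lai_max, h_init = h_init,
                 obs_days = obs_days, obs_depths = obs_depths,
                 noise_sd = noise_sd, seed = seed),
            class = "scenario_spec")
}

# fixture soil: loam-like van Genuchten constants (fixture convention)
.fixture_soil <- function(z_max) {
  soil_profile(list(vg_model(0.05, 0.45, alpha = 2, n = 1.8, K_s = 1e-6)),
               depths = z_max)
}

#' Generate a synthetic scenario
#'
#' Builds the input bundle (soil profile, grid, initial theta, weather) and
#' the hidden truth record for parameter-recovery experiments.  The same
#' seed always yields identical inputs; with `dir` given, the four input
#' files are also written in the package's dialects and byte-identical
#' across calls.
#'
#' @param spec a [scenario_spec()]
#' @param dir optional directory to write soil/INITF/WEA2 files into
#' @return list with `profile`, `grid`, `init_theta`, `weather`, `uptake`
#'   (the truth configuration), `truth` (beta, zr_max) and `paths` (when
#'   `dir` was given)
#' @export
make_scenario <- function(spec, dir = NULL) {
  if (!inherits(spec, "scenario_spec"))
    stop_domain("spec must be a scenario_spec")
  grid <- flow_grid(spec$nz, spec$dz)
  profile <- .fixture_soil(grid$z_max)
  model <- profile$models[[1]]
  init_theta <- rep(theta_of_h(model, spec$h_init), grid$nz)

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)

  day <- seq(spec$start_day, length.out = spec$days)
  frac <- (seq_len(spec$days) - 1) / max(1, spec$days - 1)
  et0 <- if (spec$et0_base + spec$et0_amp > 0)
    pmax(0, spec$et0_base + spec$et0_amp * sin(pi * frac) +
            rnorm(spec$days, 0, 0.2))
  else numeric(spec$days)
  rain <- numeric(spec$days)
  if (spec$rain_mean_depth > 0 && spec$rain_mean_interval > 0) {
    t_next <- 1 + rexp(1, 1 / spec$rain_mean_interval)
    while (t_next <= spec$days) {
      i <- ceiling(t_next)
      rain[i] <- rain[i] + rexp(1, 1 / spec$rain_mean_depth)
      t_next <- t_next + max(1, rexp(1, 1 / spec$rain_mean_interval))
    }
    rain <- pmin(rain, 40)   # keep pulses below the infiltration capacity
  }
  gf <- pmin(1, pmax(0, (day - spec$jthaw) / (spec$jmatur - spec$jthaw)))
  lai <- 0.2 + (spec$lai_max - 0.2) * gf
  tair <- 12 + 10 * sin(pi * frac) + rnorm(spec$days, 0, 1.5)
  rh <- pmin(0.95, pmax(0.2, 0.55 + 0.15 * (rain > 0) +
                               rnorm(spec$days, 0, 0.05)))
  weather <- data.frame(day = day, et0 = et0, tair = tair, rain = rain,
                        rh = rh, lai = lai)
  uptake <- uptake_config(icps = spec$icps, beta = spec$beta,
                          zr_max = spec$zr_max, jthaw = spec$jthaw,
                          jmatur = spec$jmatur, l0 = spec$dz)
  out <- list(profile = profile, grid = grid, init_theta = init_theta,
              weather = weather, uptake = uptake,
              truth = c(beta = spec$beta, zr_max = spec$zr_max),
              spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$paths <- c(
      soil = write_soil(profile, grid, file.path(dir, "SOIL.DAT")),
      init = write_init(init_theta, file.path(dir, "INITF.DAT")),
      weather = write_weather(weather, file.path(dir, "WEA2.DAT")))
  }
  out
}

#' Synthesize noisy observations from a simulation
#'
#' Samples the simulated water content at the plan's (day, depth) points
#' and applies seeded multiplicative noise: theta_obs = theta_sim *
#' (1 + eps), eps ~ N(0, sd).  With sd = 0 the observations equal the
#' simulated values exactly.
#'
#' @param run an `als_run`
#' @param days observation days (must lie within the simulated window)
#' @param depths observation depths (m, matched to nearest block center)
#' @param sd multiplicative noise standard deviation
#' @param seed RNG seed
#' @return data.frame with day, depth, theta
#' @export
synthesize_observations <- function(run, days, depths, sd = 0,
                                    seed = 1) {
  di <- match(days, run$days)
  if (anyNA(di))
    stop_domain("observation day %g outside the simulated window",
                days[which(is.na(di))[1]])
  plan <- expand.grid(day = days, depth = depths)
  zi <- vapply(plan$depth, function(d) which.min(abs(run$grid$z - d)),
               integer(1))
  sim <- run$theta[cbind(match(plan$day, run$days), zi)]
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  eps <- if (sd > 0) rnorm(nrow(plan), 0, sd) else numeric(nrow(plan))
  data.frame(day = plan$day, depth = plan$depth,
             theta = sim * (1 + eps))
}
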
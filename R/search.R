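#' Search lattice for the root-parameter grid search
#'
#' Defaults reproduce the documented lattices: 16 beta values from 0.5 in
#' steps of 0.25 (up to 4.25) and 22 maximum rooting depths from 0.75 m in
#' steps of 0.05 m (up to 1.80 m), i.e. 352 simulations.
#'
#' @param betas strictly increasing beta values
#' @param zrmaxs strictly increasing maximum rooting depths (m)
#' @return a list of class `search_grid`
#' @export
search_grid <- function(betas = seq(0.5, by = 0.25, length.out = 16),
                        zrmaxs = seq(0.75, by = 0.05, length.out = 22)) {
  if (!length(betas) || !length(zrmaxs))
    stop_domain("search grid must be non-empty")
  if (any(diff(betas) <= 0) || any(diff(zrmaxs) <= 0))
    stop_domain("search grid values must be strictly increasing")
  structure(list(betas = betas, zrmaxs = zrmaxs),
            class = "search_grid")
}

#' Average relative discrepancy between simulated and measured theta
#'
#' ARD = mean over all observations of |theta_sim - theta_obs| / theta_obs,
#' pooled across days and depths.  Observation depths are matched to the
#' nearest block center; days are matched exactly against the simulated
#' days (observations with day = NA are taken on the last simulated day).
#'
#' @param run an `als_run`
#' @param obs data.frame with columns day, depth, theta
#' @return dimensionless non-negative score, zero iff an exact match
#' @export
ard_score <- function(run, obs) {
  if (!nrow(obs)) stop_domain("no observations to score")
  if (any(obs$theta <= 0))
    stop_domain("invalid observation: theta must be > 0")
  day <- obs$day
  day[is.na(day)] <- run$days[length(run$days)]
  di <- match(day, run$days)
  if (anyNA(di))
    stop_domain("observation day %g outside the simulated window",
                day[which(is.na(di))[1]])
  zi <- vapply(obs$depth, function(d) which.min(abs(run$grid$z - d)),
               integer(1))
  sim <- run$theta[cbind(di, zi)]
  mean(abs(sim - obs$theta) / obs$theta)
}

#' Simulation-based grid search for root parameters
#'
#' Runs one independent full simulation per (beta, zr_max) lattice point --
#' no state is shared between runs -- scores each against the measured
#' water contents with [ard_score()], and collects the seven summary grids
#' (ARD plus the run ledgers).  A failing cell is recorded as NA with its
#' diagnostic message rather than aborting the sweep.
#'
#' @param profile a [soil_profile()]
#' @param grid a [flow_grid()]
#' @param init_theta initial per-block water content
#' @param weather weather data.frame
#' @param obs observations data.frame (day, depth, theta)
#' @param sgrid a [search_grid()]
#' @param uptake template [uptake_config()]; beta and zr_max are replaced
#'   per lattice point
#' @param control a [run_control()]
#' @return an object of class `als_search`: matrices `ard`, `c_aeva`,
#'   `c_atra`, `wbelow`, `wadd`, `bigi`, `pctdif` (rows = betas, columns =
#'   zrmaxs), the lattice vectors, `argmin` (the (beta, zr_max) pair
#'   minimizing ARD) and a list of per-cell failure messages
#' @export
run_search <- function(profile, grid, init_theta, weather, obs,
                       sgrid = search_grid(), uptake = uptake_config(),
                       control = run_control()) {
  if (!inherits(sgrid, "search_grid"))
    stop_domain("sgrid must be a search_grid")
  nb <- length(sgrid$betas); nzr <- length(sgrid$zrmaxs)
  mk <- function() matrix(NA_real_, nb, nzr,
                          dimnames = list(beta = sgrid$betas,
                                          zr = sgrid$zrmaxs))
  ard <- c_aeva <- c_atra <- wbelow <- wadd <- bigi <- pctdif <- mk()
  failures <- list()
  for (i in seq_len(nb)) for (j in seq_len(nzr)) {
    cfg <- uptake
    cfg$beta <- sgrid$betas[i]
    cfg$zr_max <- sgrid$zrmaxs[j]
    res <- tryCatch({
      run <- run_simulation(profile, grid, init_theta, weather, cfg,
                            control)
      list(ard = ard_score(run, obs), lg = run$ledger)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[sprintf("beta=%g,zr=%g", cfg$beta, cfg$zr_max)]] <-
        conditionMessage(res)
    } else {
      ard[i, j] <- res$ard
      c_aeva[i, j] <- res$lg$C_AEVA
      c_atra[i, j] <- res$lg$C_ATRA
      wbelow[i, j] <- res$lg$WBELOW
      wadd[i, j] <- res$lg$WADD
      bigi[i, j] <- res$lg$BIGI
      pctdif[i, j] <- res$lg$PCTDIF
    }
  }
  argmin <- if (all(is.na(ard))) c(beta = NA_real_, zr_max = NA_real_)
  else {
    ij <- which(ard == min(ard, na.rm = TRUE), arr.ind = TRUE)[1, ]
    c(beta = sgrid$betas[ij[1]], zr_max = sgrid$zrmaxs[ij[2]])
  }
  structure(list(betas = sgrid$betas, zrmaxs = sgrid$zrmaxs, ard = ard,
                 c_aeva = c_aeva, c_atra = c_atra, wbelow = wbelow,
                 wadd = wadd, bigi = bigi, pctdif = pctdif,
                 argmin = argmin, failures = failures),
            class = "als_search")
}

#' @export
print.als_search <- function(x, ...) {
  cat(sprintf("<als_search: %d x %d lattice (%d runs, %d failed)>\n",
              length(x$betas), length(x$zrmaxs),
              length(x$betas) * length(x$zrmaxs), length(x$failures)))
  if (!is.na(x$argmin[["beta"]]))
    cat(sprintf("  argmin ARD = %.5g at beta = %g, zr_max = %g m\n",
                min(x$ard, na.rm = TRUE), x$argmin[["beta"]],
                x$argmin[["zr_max"]]))
  invisible(x)
}
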
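#' Partition potential ET into soil evaporation and transpiration
#'
#' Beer's-law canopy partition: Tp = et0 * (1 - exp(-k_ext * lai)),
#' Ep = et0 - Tp, so Ep + Tp = et0 exactly.  Bare soil (lai = 0) routes all
#' demand to evaporation; a closed canopy routes it to transpiration.
#'
#' @param et0 daily potential evapotranspiration (mm/day), vectorized
#' @param lai leaf area index (>= 0), vectorized
#' @param k_ext canopy extinction coefficient (> 0, default 0.5)
#' @return list with `Ep` and `Tp` (mm/day)
#' @export
partition_et <- function(et0, lai, k_ext = 0.5) {
  if (k_ext <= 0) stop_domain("k_ext must be > 0")
  if (any(et0 < 0) || any(lai < 0)) stop_domain("et0 and lai must be >= 0")
  Tp <- et0 * (1 - exp(-k_ext * lai))
  list(Ep = et0 - Tp, Tp = Tp)
}

#' Soil-limited actual evaporation
#'
#' Stage-2 limiting: actual evaporation is the smaller of the energy-limited
#' demand Ep and the Darcy exfiltration capacity of the surface block toward
#' a prescribed air-dry surface head (half-block spacing from the surface to
#' the first block center); never negative.
#'
#' @param Ep potential soil evaporation (mm/day)
#' @param h1 pressure head of the surface block (m)
#' @param model hydraulic model of the surface block
#' @param dz block thickness (m)
#' @param h_dry air-dry surface head (m, default -1000)
#' @return actual evaporation (mm/day)
#' @export
evaporation_limit <- function(Ep, h1, model, dz, h_dry = -1000) {
  if (Ep < 0) stop_domain("Ep must be >= 0")
  K1 <- K_of_theta(model, theta_of_h(model, h1))
  J_dry <- -K1 * (h1 - h_dry) / (0.5 * dz) + K1   # positive downward
  capacity <- max(0, -J_dry) * 86400000           # upward flux -> mm/day
  min(Ep, capacity)
}

#' Net surface flux from rain and actual evaporation
#'
#' J(0,t) = (rain - actualE) / 86400000 m/s, positive downward; rain and
#' evaporation act only through their net within a step.
#'
#' @param rain daily rainfall (mm/day)
#' @param actualE actual evaporation (mm/day)
#' @return surface flux (m/s)
#' @export
surface_flux <- function(rain, actualE) {
  (rain - actualE) / 86400000
}
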
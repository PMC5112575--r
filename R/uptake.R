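#' Stress-threshold option sets for the ending water potential
#'
#' Three (h31, h32) pairs for the transpiration-dependent ending water
#' potential of optimal uptake, all tied to the reference transpiration
#' rates Tp1 = 1 and Tp2 = 5 mm/day: set 1 (-11, -5) m, set 2 (-14, -8) m,
#' set 3 (-16, -10) m.
#'
#' @param ihth option selector, 1, 2 or 3
#' @return named numeric vector with h31 and h32 (m)
#' @export
h3_options <- function(ihth) {
  sets <- list(c(h31 = -11, h32 = -5),
               c(h31 = -14, h32 = -8),
               c(h31 = -16, h32 = -10))
  if (!ihth %in% 1:3)
    stop_domain("ihth must be one of {1, 2, 3}, got %s", format(ihth))
  sets[[ihth]]
}

#' Transpiration-dependent ending water potential h3
#'
#' h3 = a*Tp + h31 - a*Tp1 with a = (h31 - h32)/(Tp1 - Tp2), so that
#' h3 = h31 at the slow rate Tp1 and h32 at the fast rate Tp2, linear in
#' between and clamped to the endpoint values outside `[Tp1, Tp2]`.
#'
#' @param Tp potential transpiration (mm/day, >= 0), vectorized
#' @param ihth option set selector (used when h31/h32 not given)
#' @param h31,h32 endpoint heads (m), overriding `ihth`
#' @param Tp1,Tp2 reference transpiration rates (mm/day)
#' @return h3 (m)
#' @export
#' @examples
#' h3_of_tp(1)   # -11
#' h3_of_tp(3)   # -8
h3_of_tp <- function(Tp, ihth = 1, h31 = NULL, h32 = NULL,
                     Tp1 = 1, Tp2 = 5) {
  if (is.null(h31) || is.null(h32)) {
    opt <- h3_options(ihth)
    h31 <- opt[["h31"]]; h32 <- opt[["h32"]]
  }
  if (any(Tp < 0)) stop_domain("Tp must be >= 0")
  a <- (h31 - h32) / (Tp1 - Tp2)
  out <- a * Tp + h31 - a * Tp1
  out[Tp <= Tp1] <- h31
  out[Tp >= Tp2] <- h32
  out
}

#' Feddes stress-reduction factor alpha(h)
#'
#' Trapezoidal reduction of root uptake: zero at and above the anaerobiosis
#' point h1, rising linearly to 1 at h2, optimal on `[h3, h2]`, falling
#' linearly to zero at the permanent wilting point h4 and below.  Heads are
#' ordered h1 >= h2 >= h3 >= h4 (all <= 0).
#'
#' @param h pressure head (m), vectorized
#' @param h1,h2,h3,h4 threshold heads (m)
#' @return dimensionless factor in `[0, 1]`
#' @export
stress_alpha <- function(h, h1, h2, h3, h4) {
  if (!(h1 >= h2 && h2 >= h3 && h3 >= h4))
    stop_domain("need h1 >= h2 >= h3 >= h4 (got %g, %g, %g, %g)",
                h1, h2, h3, h4)
  out <- numeric(length(h))
  rise <- h < h1 & h > h2
  out[rise] <- (h1 - h[rise]) / (h1 - h2)
  out[h <= h2 & h >= h3] <- 1
  fall <- h < h3 & h > h4
  out[fall] <- (h[fall] - h4) / (h3 - h4)
  out
}

#' Root uptake configuration
#'
#' Validated bundle of all sink-term parameters: the uptake model selector
#' ICPS (1 = power-law root distribution with shape factor beta;
#' 2 = compensated uptake with the cubic normalized root density;
#' 3 = cubic density, proportional allocation, no compensation), the growth
#' calendar (Julian days JTHAW to JMATUR, linear root deepening from the
#' seed depth l0 to zr_max), the stress thresholds, and the compensation
#' exponent lambda (admissible range 0.01 to 2.0).
#'
#' @param icps uptake model selector, 1 (default), 2 or 3
#' @param ihth ending-potential option set, 1 (default), 2 or 3
#' @param beta root distribution shape factor (> 0)
#' @param zr_max maximum rooting depth (m, > 0)
#' @param jthaw,jmatur Julian days of growth initiation and maturity
#' @param lambda compensation exponent, in `[0.01, 2.0]`
#' @param r_coeffs cubic root-density coefficients R1..R4
#' @param h1,h2,h4 fixed stress thresholds (m); h3 is transpiration-dependent
#' @param l0 seed root depth (m) before JTHAW; defaults to one block when
#'   the simulation grid is known, else 0.05 m
#' @param tp1,tp2 reference transpiration rates (mm/day) for h3
#' @return an object of class `uptake_config`
#' @export
uptake_config <- function(icps = 1, ihth = 1, beta = 1, zr_max = 1,
                          jthaw = 110, jmatur = 190, lambda = 1,
                          r_coeffs = c(2.21, -3.72, 3.46, -1.87),
                          h1 = -0.1, h2 = -0.25, h4 = -150,
                          l0 = 0.05, tp1 = 1, tp2 = 5) {
  if (!icps %in% 1:3)
    stop_domain("icps must be one of {1, 2, 3}, got %s", format(icps))
  opt <- h3_options(ihth)
  if (beta <= 0) stop_domain("beta must be > 0")
  if (zr_max <= 0) stop_domain("zr_max must be > 0")
  if (jthaw >= jmatur)
    stop_domain("need jthaw < jmatur (got %d >= %d)", jthaw, jmatur)
  if (lambda < 0.01 || lambda > 2.0)
    stop_domain("lambda must lie in [0.01, 2.0], got %g", lambda)
  if (length(r_coeffs) != 4) stop_domain("r_coeffs must have 4 elements")
  if (!(h1 <= 0 && h1 >= h2))
    stop_domain("need 0 >= h1 >= h2 (got h1 = %g, h2 = %g)", h1, h2)
  if (h2 < opt[["h31"]])
    stop_domain("h2 (%g) must lie above the h3 range (h31 = %g)",
                h2, opt[["h31"]])
  if (h4 > opt[["h32"]])
    stop_domain("h4 (%g) must lie below the h3 range (h32 = %g)",
                h4, opt[["h32"]])
  if (l0 <= 0 || l0 > zr_max) stop_domain("need 0 < l0 <= zr_max")
  structure(list(icps = as.integer(icps), ihth = as.integer(ihth),
                 beta = beta, zr_max = zr_max,
                 jthaw = as.integer(jthaw), jmatur = as.integer(jmatur),
                 lambda = lambda, r_coeffs = r_coeffs,
                 h1 = h1, h2 = h2, h4 = h4,
                 h31 = opt[["h31"]], h32 = opt[["h32"]],
                 tp1 = tp1, tp2 = tp2, l0 = l0),
            class = "uptake_config")
}

#' @export
print.uptake_config <- function(x, ...) {
  model <- c("power-law distribution (beta)",
             "compensated uptake (lambda, cubic density)",
             "cubic density, no compensation")[x$icps]
  cat(sprintf("<uptake_config: ICPS = %d, %s>\n", x$icps, model))
  cat(sprintf("  beta = %g, zr_max = %g m, lambda = %g\n",
              x$beta, x$zr_max, x$lambda))
  cat(sprintf("  growth: day %d -> %d (l0 = %g m)\n",
              x$jthaw, x$jmatur, x$l0))
  cat(sprintf("  thresholds (m): h1 = %g, h2 = %g, h3 in [%g, %g], h4 = %g\n",
              x$h1, x$h2, x$h31, x$h32, x$h4))
  invisible(x)
}

#' Root depth over the growing season
#'
#' Piecewise linear: the seed depth l0 up to JTHAW, zr_max from JMATUR on,
#' linear in between.
#'
#' @param day Julian day-of-year, vectorized
#' @param cfg an [uptake_config()]
#' @return rooting depth (m)
#' @export
root_depth <- function(day, cfg) {
  f <- pmin(1, pmax(0, (day - cfg$jthaw) / (cfg$jmatur - cfg$jthaw)))
  cfg$l0 + f * (cfg$zr_max - cfg$l0)
}

#' Normalized root density (cubic polynomial)
#'
#' L_nrd(z_r) = R1 + R2*z_r + R3*z_r^2 + R4*z_r^3 on normalized depth
#' z_r in `[0, 1]`, floored at zero (a density cannot be negative).  The
#' default coefficients are fitted values for wheat.
#'
#' @param z_r normalized depth in `[0, 1]`, vectorized
#' @param r_coeffs coefficients R1..R4
#' @return dimensionless density, >= 0
#' @export
lnrd_wu <- function(z_r, r_coeffs = c(2.21, -3.72, 3.46, -1.87)) {
  if (any(z_r < 0 | z_r > 1)) stop_domain("z_r must lie in [0, 1]")
  pmax(0, r_coeffs[1] + r_coeffs[2] * z_r + r_coeffs[3] * z_r^2 +
          r_coeffs[4] * z_r^3)
}

# mm/day -> m/s: 86400 s/day * 1000 mm/m
UNIT_FACTOR <- 86400000

.sink_result <- function(S, grid) {
  structure(list(S = S,
                 actual_transpiration = sum(S * grid$dz) * UNIT_FACTOR),
            class = "sink_profile")
}

#' @export
print.sink_profile <- function(x, ...) {
  cat(sprintf("<sink_profile: %d blocks, actual transpiration %.4g mm/day>\n",
              length(x$S), x$actual_transpiration))
  invisible(x)
}

.alpha_blocks <- function(h, cfg, h3) {
  stress_alpha(h, cfg$h1, cfg$h2, h3, cfg$h4)
}

#' Sink profile from the power-law root distribution (ICPS = 1)
#'
#' S_i = alpha(h_i) * Tp * (beta + 1) * (1 - z_i/L)^beta / (86400000 * L)
#' for block centers z_i <= L, zero below the root zone.  The normalized
#' density (beta + 1)(1 - z/L)^beta / L integrates to one over the root
#' zone, so with alpha = 1 the total uptake equals Tp up to discretization.
#'
#' @param h per-block pressure heads (m)
#' @param grid a [flow_grid()]
#' @param Tp potential transpiration (mm/day)
#' @param L current rooting depth (m, > 0)
#' @param cfg an [uptake_config()]
#' @param h3 ending potential (m); defaults to h3_of_tp(Tp) under cfg
#' @return a `sink_profile`: per-block S (1/s) and the implied actual
#'   transpiration (mm/day)
#' @export
sink_prasad <- function(h, grid, Tp, L, cfg, h3 = NULL) {
  if (L <= 0) stop_domain("rooting depth L must be > 0")
  if (Tp < 0) stop_domain("Tp must be >= 0")
  if (is.null(h3)) h3 <- h3_of_tp(Tp, h31 = cfg$h31, h32 = cfg$h32,
                                  Tp1 = cfg$tp1, Tp2 = cfg$tp2)
  S <- numeric(grid$nz)
  inroot <- grid$z <= L
  if (Tp > 0 && any(inroot)) {
    a <- .alpha_blocks(h[inroot], cfg, h3)
    S[inroot] <- a * Tp * (cfg$beta + 1) *
      (1 - grid$z[inroot] / L)^cfg$beta / (UNIT_FACTOR * L)
  }
  .sink_result(S, grid)
}

#' Sink profile from the cubic density without compensation (ICPS = 3)
#'
#' Potential transpiration is allocated over the root zone in proportion to
#' the discrete normalized cubic density and then reduced block-wise by
#' alpha: S_i = alpha_i * Tp * w_i / (86400000 * dz * sum(w)), where
#' w_j = L_nrd(z_j / Zr) * dz.  With alpha = 1 everywhere the total uptake
#' equals Tp exactly; stressed blocks lose uptake with no redistribution.
#'
#' @inheritParams sink_prasad
#' @param Zr current rooting depth (m, > 0)
#' @export
sink_wu <- function(h, grid, Tp, Zr, cfg, h3 = NULL) {
  if (Zr <= 0) stop_domain("rooting depth Zr must be > 0")
  if (is.null(h3)) h3 <- h3_of_tp(Tp, h31 = cfg$h31, h32 = cfg$h32,
                                  Tp1 = cfg$tp1, Tp2 = cfg$tp2)
  S <- numeric(grid$nz)
  inroot <- grid$z <= Zr
  w <- numeric(grid$nz)
  w[inroot] <- lnrd_wu(grid$z[inroot] / Zr, cfg$r_coeffs) * grid$dz
  if (sum(w) <= 0)
    stop_domain("all root-density weights are zero: no roots in the profile")
  if (Tp > 0) {
    a <- .alpha_blocks(h, cfg, h3)
    S <- a * Tp * w / (UNIT_FACTOR * grid$dz * sum(w))
  }
  .sink_result(S, grid)
}

#' Compensated sink profile (ICPS = 2)
#'
#' The compensation form
#' S_i = alpha_i^2 * L_nrd,i^lambda * Tp / (dz_i * sum_j alpha_j * L_nrd,j^lambda),
#' converted to 1/s with the 86400000 factor.  Total uptake over the root
#' zone is Tp * sum(alpha^2 L^lambda) / sum(alpha L^lambda): equal to Tp
#' whenever the in-root alpha are all 0 or 1 with at least one wet block
#' (full compensation), a * Tp under uniform stress a.  If every alpha is
#' zero the profile is all zeros (full stress), flagged via the
#' `full_stress` attribute rather than an error.
#'
#' @inheritParams sink_wu
#' @export
sink_li_yadav <- function(h, grid, Tp, Zr, cfg, h3 = NULL) {
  if (Zr <= 0) stop_domain("rooting depth Zr must be > 0")
  if (is.null(h3)) h3 <- h3_of_tp(Tp, h31 = cfg$h31, h32 = cfg$h32,
                                  Tp1 = cfg$tp1, Tp2 = cfg$tp2)
  S <- numeric(grid$nz)
  inroot <- grid$z <= Zr
  Lv <- numeric(grid$nz)
  Lv[inroot] <- lnrd_wu(grid$z[inroot] / Zr, cfg$r_coeffs)
  a <- .alpha_blocks(h, cfg, h3)
  pos <- Lv > 0
  denom <- sum(a[pos] * Lv[pos]^cfg$lambda)
  full_stress <- FALSE
  if (Tp > 0 && denom > 0) {
    S[pos] <- a[pos]^2 * Lv[pos]^cfg$lambda * Tp /
      (UNIT_FACTOR * grid$dz * denom)
  } else if (Tp > 0) full_stress <- TRUE
  out <- .sink_result(S, grid)
  attr(out, "full_stress") <- full_stress
  out
}

#' Sink dispatch over the uptake model selector
#'
#' Refreshes h3 from the day's potential transpiration, evaluates the root
#' depth for the day, and dispatches on ICPS.
#'
#' @param h per-block pressure heads (m)
#' @param grid a [flow_grid()]
#' @param Tp potential transpiration (mm/day)
#' @param day Julian day-of-year
#' @param cfg an [uptake_config()]
#' @return a `sink_profile`
#' @export
compute_sink <- function(h, grid, Tp, day, cfg) {
  if (!inherits(cfg, "uptake_config"))
    stop_domain("cfg must be an uptake_config")
  h3 <- h3_of_tp(Tp, h31 = cfg$h31, h32 = cfg$h32,
                 Tp1 = cfg$tp1, Tp2 = cfg$tp2)
  L <- root_depth(day, cfg)
  switch(cfg$icps,
         sink_prasad(h, grid, Tp, L, cfg, h3 = h3),
         sink_li_yadav(h, grid, Tp, L, cfg, h3 = h3),
         sink_wu(h, grid, Tp, L, cfg, h3 = h3))
}
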
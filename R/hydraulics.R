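#' Van Genuchten-Mualem hydraulic model
#'
#' Closed-form soil water retention and unsaturated conductivity for one
#' soil layer: theta(h) = theta_r + (theta_s - theta_r) * (1 + (alpha*|h|)^n)^(-m)
#' with m = 1 - 1/n, and Mualem conductivity
#' K(Se) = K_s * Se^0.5 * (1 - (1 - Se^(1/m))^m)^2 where Se is effective
#' saturation.  Heads h >= 0 are saturated: theta = theta_s, capacity 0.
#'
#' @param theta_r residual water content (m3/m3)
#' @param theta_s saturated water content (m3/m3)
#' @param alpha van Genuchten alpha (1/m)
#' @param n van Genuchten n (dimensionless, > 1)
#' @param K_s saturated hydraulic conductivity (m/s)
#' @return an object of class `c("vg_model", "hydraulic_model")`
#' @export
#' @examples
#' m <- vg_model(0.05, 0.45, alpha = 2, n = 2, K_s = 1e-6)
#' theta_of_h(m, -0.5)
vg_model <- function(theta_r, theta_s, alpha, n, K_s) {
  if (!(theta_r >= 0 && theta_s > theta_r && theta_s <= 1))
    stop_domain("need 0 <= theta_r < theta_s <= 1 (got %g, %g)",
                theta_r, theta_s)
  if (alpha <= 0 || n <= 1) stop_domain("need alpha > 0 and n > 1")
  if (K_s <= 0) stop_domain("need K_s > 0")
  structure(list(form = 1L, theta_r = theta_r, theta_s = theta_s,
                 K_s = K_s, alpha = alpha, n = n, m = 1 - 1 / n),
            class = c("vg_model", "hydraulic_model"))
}

#' Tabulated hydraulic model
#'
#' Piecewise-linear retention and conductivity curves given as paired
#' monotone samples, with flat extrapolation beyond the end nodes.  The
#' wettest tabulated water content acts as theta_s and the driest as
#' theta_r; heads h >= 0 return theta_s.
#'
#' @param h tabulated pressure heads (m, <= 0), any order
#' @param theta water contents (m3/m3) paired with `h`
#' @param K conductivities (m/s) paired with `theta`
#' @return an object of class `c("tabulated_model", "hydraulic_model")`
#' @export
tabulated_model <- function(h, theta, K) {
  if (length(h) < 2 || length(theta) != length(h) || length(K) != length(h))
    stop_domain("tabulated model needs >= 2 rows of equal-length h, theta, K")
  o <- order(h)
  h <- h[o]; theta <- theta[o]; K <- K[o]
  if (anyDuplicated(h)) stop_domain("duplicate h nodes in tabulated model")
  if (any(diff(theta) < 0))
    stop_domain("theta must be non-decreasing in h for a tabulated model")
  if (any(diff(theta) == 0))
    stop_domain("theta nodes must be strictly increasing (invertibility)")
  if (any(K < 0) || any(diff(K) < 0))
    stop_domain("K must be non-negative and non-decreasing in theta")
  structure(list(form = 2L, theta_r = theta[1],
                 theta_s = theta[length(theta)],
                 K_s = K[length(K)],
                 tab_h = h, tab_theta = theta,
                 tab_kt = theta, tab_k = K),
            class = c("tabulated_model", "hydraulic_model"))
}

#' @export
print.hydraulic_model <- function(x, ...) {
  cat(sprintf("<hydraulic_model: %s>\n",
              if (x$form == 1L) "van Genuchten-Mualem" else "tabulated"))
  cat(sprintf("  theta_r = %.4g  theta_s = %.4g  K_s = %.4g m/s\n",
              x$theta_r, x$theta_s, x$K_s))
  if (x$form == 1L)
    cat(sprintf("  alpha = %.4g 1/m  n = %.4g  m = %.4g\n",
                x$alpha, x$n, x$m))
  else
    cat(sprintf("  %d tabulated nodes, h in [%g, %g] m\n",
                length(x$tab_h), min(x$tab_h), max(x$tab_h)))
  invisible(x)
}

.flat_approx <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}

#' Water content from pressure head
#'
#' Total function: saturated (h >= 0) returns theta_s; very dry heads tend
#' to theta_r.
#'
#' @param model a [vg_model()] or [tabulated_model()]
#' @param h pressure head (m), vectorized
#' @return water content (m3/m3)
#' @export
theta_of_h <- function(model, h) UseMethod("theta_of_h")

#' @export
theta_of_h.vg_model <- function(model, h) {
  out <- rep(model$theta_s, length(h))
  u <- h < 0
  if (any(u)) {
    ahn <- (model$alpha * (-h[u]))^model$n
    out[u] <- model$theta_r +
      (model$theta_s - model$theta_r) * (1 + ahn)^(-model$m)
  }
  out
}

#' @export
theta_of_h.tabulated_model <- function(model, h) {
  out <- rep(model$theta_s, length(h))
  u <- h < 0
  if (any(u)) out[u] <- .flat_approx(model$tab_h, model$tab_theta, h[u])
  out
}

#' Pressure head from water content (retention-curve inversion)
#'
#' @param model a hydraulic model
#' @param theta water content (m3/m3); must lie in (theta_r, theta_s]
#' @return pressure head (m); 0 at saturation
#' @export
h_of_theta <- function(model, theta) UseMethod("h_of_theta")

.check_theta_range <- function(model, theta, strict_lower = TRUE) {
  lo_bad <- if (strict_lower) theta <= model$theta_r else
    theta < model$theta_r - 1e-12
  if (any(lo_bad) || any(theta > model$theta_s + 1e-12))
    stop_domain(
      "theta = %g outside (%g, %g] for this layer's retention curve",
      theta[which(lo_bad | theta > model$theta_s + 1e-12)[1]],
      model$theta_r, model$theta_s)
}

#' @export
h_of_theta.vg_model <- function(model, theta) {
  .check_theta_range(model, theta)
  out <- numeric(length(theta))
  u <- theta < model$theta_s
  if (any(u)) {
    Se <- (theta[u] - model$theta_r) / (model$theta_s - model$theta_r)
    out[u] <- -(1 / model$alpha) * (Se^(-1 / model$m) - 1)^(1 / model$n)
  }
  out
}

#' @export
h_of_theta.tabulated_model <- function(model, theta) {
  .check_theta_range(model, theta, strict_lower = FALSE)
  out <- rep(model$tab_h[length(model$tab_h)], length(theta))
  u <- theta < model$theta_s
  if (any(u)) out[u] <- .flat_approx(model$tab_theta, model$tab_h, theta[u])
  out
}

#' Hydraulic conductivity from water content
#'
#' @param model a hydraulic model
#' @param theta water content (m3/m3) in `[theta_r, theta_s]`
#' @return conductivity (m/s), non-decreasing in theta, K(theta_s) = K_s
#' @export
K_of_theta <- function(model, theta) UseMethod("K_of_theta")

#' @export
K_of_theta.vg_model <- function(model, theta) {
  if (any(theta < model$theta_r - 1e-12) ||
      any(theta > model$theta_s + 1e-12))
    stop_domain("theta outside [theta_r, theta_s] in K_of_theta")
  Se <- pmin(1, pmax(0, (theta - model$theta_r) /
                        (model$theta_s - model$theta_r)))
  out <- numeric(length(theta))
  p <- Se > 0
  t <- 1 - (1 - Se[p]^(1 / model$m))^model$m
  out[p] <- model$K_s * sqrt(Se[p]) * t^2
  out
}

#' @export
K_of_theta.tabulated_model <- function(model, theta) {
  if (any(theta < model$theta_r - 1e-12) ||
      any(theta > model$theta_s + 1e-12))
    stop_domain("theta outside [theta_r, theta_s] in K_of_theta")
  .flat_approx(model$tab_kt, model$tab_k, theta)
}

#' Soil water capacity c(h) = d(theta)/dh
#'
#' Analytic derivative of the closed-form retention curve, or the slope of
#' the active segment for a tabulated curve.  Zero for h >= 0 (saturated)
#' and beyond tabulated end nodes.
#'
#' @param model a hydraulic model
#' @param h pressure head (m), vectorized
#' @return capacity (1/m), >= 0
#' @export
water_capacity <- function(model, h) UseMethod("water_capacity")

#' @export
water_capacity.vg_model <- function(model, h) {
  out <- numeric(length(h))
  u <- h < 0
  if (any(u)) {
    a <- model$alpha; n <- model$n; m <- model$m
    ahn <- (a * (-h[u]))^n
    out[u] <- (model$theta_s - model$theta_r) * a * n * m *
      (a * (-h[u]))^(n - 1) * (1 + ahn)^(-m - 1)
  }
  out
}

#' @export
water_capacity.tabulated_model <- function(model, h) {
  vapply(h, function(hh) {
    x <- model$tab_h
    if (hh >= 0 || hh <= x[1] || hh >= x[length(x)]) return(0)
    i <- findInterval(hh, x)
    (model$tab_theta[i + 1] - model$tab_theta[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}

#' Layered soil profile
#'
#' An ordered stack of layers, each a hydraulic model with a bottom depth;
#' the last bottom depth is the total profile depth z_max.
#'
#' @param models list of hydraulic models, top layer first
#' @param depths bottom depth of each layer (m, strictly increasing)
#' @return an object of class `soil_profile`
#' @export
soil_profile <- function(models, depths) {
  if (length(models) != length(depths) || length(models) < 1)
    stop_domain("need one bottom depth per layer")
  if (any(depths <= 0) || any(diff(depths) <= 0))
    stop_domain("layer bottom depths must be positive, strictly increasing")
  for (m in models)
    if (!inherits(m, "hydraulic_model"))
      stop_domain("every layer must be a hydraulic_model")
  structure(list(models = models, depths = depths,
                 z_max = depths[length(depths)]),
            class = "soil_profile")
}

#' @export
print.soil_profile <- function(x, ...) {
  cat(sprintf("<soil_profile: %d layer(s), z_max = %g m>\n",
              length(x$models), x$z_max))
  invisible(x)
}

#' Per-block hydraulic models
#'
#' Maps each grid block to the layer containing its center.
#'
#' @param profile a [soil_profile()]
#' @param grid a [flow_grid()]
#' @return list of nz hydraulic models
#' @export
block_models <- function(profile, grid) {
  if (grid$z_max > profile$z_max + 1e-9)
    stop_domain("grid deeper (%g m) than soil profile (%g m)",
                grid$z_max, profile$z_max)
  idx <- block_layer_index(profile, grid)
  profile$models[idx]
}

block_layer_index <- function(profile, grid) {
  vapply(grid$z, function(zz) which(profile$depths >= zz - 1e-12)[1],
         integer(1))
}

# flat parameter list consumed by the C++ engine
as_layer_list <- function(model) {
  if (model$form == 1L)
    list(form = 1L, theta_r = model$theta_r, theta_s = model$theta_s,
         K_s = model$K_s, alpha = model$alpha, n = model$n)
  else
    list(form = 2L, theta_r = model$theta_r, theta_s = model$theta_s,
         K_s = model$K_s, tab_h = model$tab_h, tab_theta = model$tab_theta,
         tab_kt = model$tab_kt, tab_k = model$tab_k)
}
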
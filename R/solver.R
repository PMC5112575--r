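#' Block-centered vertical grid
#'
#' The profile (depth z_max = nz * dz) is divided into nz blocks of equal
#' thickness dz; state (h, theta) lives at block centers z_i = (i - 0.5)*dz,
#' conductivities and fluxes at block edges.  Depth is positive downward
#' with the surface at zero.
#'
#' @param nz number of blocks (>= 3)
#' @param dz block thickness (m)
#' @return an object of class `flow_grid`
#' @export
flow_grid <- function(nz, dz) {
  nz <- as.integer(nz)
  if (is.na(nz) || nz < 3) stop_domain("need nz >= 3")
  if (dz <= 0) stop_domain("need dz > 0")
  structure(list(nz = nz, dz = dz, z_max = nz * dz,
                 z = (seq_len(nz) - 0.5) * dz),
            class = "flow_grid")
}

#' @export
print.flow_grid <- function(x, ...) {
  cat(sprintf("<flow_grid: nz = %d, dz = %g m, z_max = %g m>\n",
              x$nz, x$dz, x$z_max))
  invisible(x)
}

#' Profile state at a time instant
#'
#' Per-block pressure head and water content.  If `theta` is omitted it is
#' filled from the retention curves, keeping h and theta consistent.
#'
#' @param t simulation time (s)
#' @param h per-block pressure head (m)
#' @param theta per-block water content (m3/m3), optional
#' @param models per-block hydraulic models (required when theta is omitted)
#' @return an object of class `flow_state`
#' @export
flow_state <- function(t = 0, h, theta = NULL, models = NULL) {
  if (is.null(theta)) {
    if (is.null(models)) stop_domain("need models to derive theta from h")
    theta <- vapply(seq_along(h),
                    function(i) theta_of_h(models[[i]], h[i]), numeric(1))
  }
  if (length(theta) != length(h)) stop_domain("h and theta length mismatch")
  structure(list(t = t, h = h, theta = theta), class = "flow_state")
}

#' Boundary conditions for one step
#'
#' The upper boundary is either a prescribed surface flux J(0,t) (m/s,
#' positive downward) or a prescribed surface head h(0,t) (m); the lower
#' boundary is always a unit hydraulic gradient (gravity drainage, bottom
#' flux = K of the bottom block).
#'
#' @param type "flux" or "head"
#' @param value surface flux (m/s) or surface head (m)
#' @return an object of class `boundary_condition`
#' @export
boundary_condition <- function(type = c("flux", "head"), value) {
  type <- match.arg(type)
  if (!is.finite(value)) stop_domain("boundary value must be finite")
  structure(list(type = type, value = value), class = "boundary_condition")
}

#' Internode conductivity
#'
#' Conductivity at the interface between two adjacent blocks, from the two
#' block values.
#'
#' @param K_upper,K_lower block conductivities (m/s, >= 0)
#' @param method "arithmetic" (default) or "geometric" mean
#' @return interface conductivity (m/s), between the two inputs
#' @export
internode_K <- function(K_upper, K_lower,
                        method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  if (any(K_upper < 0) || any(K_lower < 0))
    stop_domain("conductivities must be non-negative")
  if (method == "geometric") sqrt(K_upper * K_lower)
  else 0.5 * (K_upper + K_lower)
}

#' Assemble the implicit tridiagonal system
#'
#' Builds the coefficients A, B, C, D of the backward-time linear system in
#' the new-time heads, with conductivities and capacities evaluated at the
#' old time.  For the flux upper boundary the surface flux is withheld from
#' the matrix pass (the trial/accept scheme applies it in the mass-balance
#' update instead); for the head upper boundary the surface-head term
#' K_half[1] * h(0,t) / dz^2 enters D[1].  The lower boundary is a unit
#' hydraulic gradient.
#'
#' @param state a [flow_state()]
#' @param grid a [flow_grid()]
#' @param models per-block hydraulic models (list of length nz)
#' @param bc a [boundary_condition()]
#' @param sink per-block uptake rate S_i (1/s, length nz)
#' @param dt time step (s, > 0)
#' @param kmean internode averaging, "arithmetic" or "geometric"
#' @return an object of class `tridiagonal_system` with fields A, B, C, D,
#'   K_half (length nz + 1 interface conductivities) and K (block values)
#' @export
assemble_system <- function(state, grid, models, bc, sink, dt,
                            kmean = c("arithmetic", "geometric")) {
  kmean <- match.arg(kmean)
  nz <- grid$nz; dz <- grid$dz
  if (dt <= 0) stop_domain("need dt > 0")
  if (length(sink) != nz)
    stop_domain("sink length %d != nz = %d", length(sink), nz)
  h <- state$h; th <- state$theta
  cv <- vapply(seq_len(nz),
               function(i) water_capacity(models[[i]], h[i]), numeric(1))
  K <- vapply(seq_len(nz),
              function(i) K_of_theta(models[[i]], th[i]), numeric(1))
  K_half <- numeric(nz + 1)
  K_half[2:nz] <- internode_K(K[1:(nz - 1)], K[2:nz], kmean)
  K_half[nz + 1] <- K[nz]
  if (bc$type == "head") {
    K_surf <- K_of_theta(models[[1]], theta_of_h(models[[1]], bc$value))
    K_half[1] <- internode_K(K_surf, K[1], kmean)
  } else K_half[1] <- 0

  dz2 <- dz^2
  A <- B <- C <- D <- numeric(nz)
  i <- 2:(nz - 1)
  A[i] <- -K_half[i] / dz2
  C[i] <- -K_half[i + 1] / dz2
  B[i] <- cv[i] / dt + (K_half[i] + K_half[i + 1]) / dz2
  D[i] <- cv[i] * h[i] / dt - (K_half[i + 1] - K_half[i]) / dz - sink[i]

  C[1] <- -K_half[2] / dz2
  if (bc$type == "flux") {
    # surface flux withheld (C2 = 0): the J(0,t) term of D[1] is dropped
    B[1] <- cv[1] / dt + K_half[2] / dz2
    D[1] <- cv[1] * h[1] / dt - (0 - K_half[2]) / dz - sink[1]
  } else {
    B[1] <- cv[1] / dt + (K_half[1] + K_half[2]) / dz2
    D[1] <- cv[1] * h[1] / dt - (K_half[2] - K_half[1]) / dz +
      K_half[1] * bc$value / dz2 - sink[1]
  }
  A[nz] <- -K_half[nz] / dz2
  C[nz] <- 0
  B[nz] <- cv[nz] / dt + K_half[nz] / dz2
  D[nz] <- cv[nz] * h[nz] / dt - (K[nz] - K_half[nz]) / dz - sink[nz]
  A[1] <- 0

  structure(list(A = A, B = B, C = C, D = D, K_half = K_half, K = K),
            class = "tridiagonal_system")
}

#' Thomas algorithm for tridiagonal systems
#'
#' O(n) forward elimination and back substitution.  Requires A[1] = 0 and
#' C[n] = 0.
#'
#' @param sys a `tridiagonal_system` (or any list with A, B, C, D)
#' @return solution vector h*
#' @export
thomas_solve <- function(sys) {
  A <- sys$A; B <- sys$B; C <- sys$C; D <- sys$D
  n <- length(B)
  if (A[1] != 0 || C[n] != 0)
    stop_domain("tridiagonal system requires A[1] = 0 and C[n] = 0")
  cp <- dp <- x <- numeric(n)
  if (abs(B[1]) < 1e-300) stop_domain("singular tridiagonal system (pivot 1)")
  cp[1] <- C[1] / B[1]
  dp[1] <- D[1] / B[1]
  if (n > 1) for (i in 2:n) {
    piv <- B[i] - A[i] * cp[i - 1]
    if (abs(piv) < 1e-300)
      stop_domain("singular tridiagonal system (pivot %d)", i)
    cp[i] <- C[i] / piv
    dp[i] <- (D[i] - A[i] * dp[i - 1]) / piv
  }
  x[n] <- dp[n]
  if (n > 1) for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

#' Interface fluxes from solved heads
#'
#' Darcy flux with gravity at the nz + 1 block edges (m/s, positive
#' downward): internal J[i+1] = -K_half * (h[i+1] - h[i]) / dz + K_half;
#' bottom flux = K of the bottom block (unit gradient); top flux is the
#' applied surface flux (flux BC) or the Darcy flux from the surface head.
#'
#' @param h_star solved heads (length nz)
#' @param grid a [flow_grid()]
#' @param K_half interface conductivities (length nz + 1); element nz + 1
#'   must already hold the bottom-block conductivity
#' @param bc a [boundary_condition()]
#' @return numeric vector of length nz + 1
#' @export
interface_fluxes <- function(h_star, grid, K_half, bc) {
  nz <- grid$nz; dz <- grid$dz
  J <- numeric(nz + 1)
  i <- 2:nz
  J[i] <- -K_half[i] * (h_star[i] - h_star[i - 1]) / dz + K_half[i]
  J[nz + 1] <- K_half[nz + 1]
  J[1] <- if (bc$type == "flux") bc$value else
    -K_half[1] * (h_star[1] - bc$value) / dz + K_half[1]
  J
}

#' Mass-balance water-content update
#'
#' theta*_i = theta_i - dt * (J[i+1] - J[i]) / dz - dt * S_i.  The column
#' storage change telescopes exactly to
#' dt * (J_top - J_bottom) - dt * sum(S) * dz.
#'
#' @param theta old water contents (length nz)
#' @param fluxes interface fluxes (length nz + 1, positive downward)
#' @param sink per-block uptake (1/s)
#' @param dt time step (s)
#' @param grid a [flow_grid()]
#' @return updated water contents
#' @export
mass_balance_update <- function(theta, fluxes, sink, dt, grid) {
  nz <- grid$nz
  if (length(theta) != nz || length(fluxes) != nz + 1 ||
      length(sink) != nz)
    stop_domain("length mismatch in mass_balance_update")
  theta - dt * diff(fluxes) / grid$dz - dt * sink
}

#' One flux-update time step
#'
#' The non-iterative trial/accept scheme: (1) solve the tridiagonal system
#' with old-time K and c, the surface flux withheld, giving HSTAR; form a
#' trial THETA from the mass balance using conductivities re-evaluated at
#' HSTAR plus the withheld surface flux; (2) accept the trial THETA in a
#' block only if the block and its immediate neighbours are unsaturated, and
#' update h there from the retention curve; (3) otherwise reject the trial,
#' accept HSTAR as h and recompute THETA from the retention curve on HSTAR.
#' The returned state satisfies theta <= theta_s per layer.
#'
#' Block 1's upper neighbour is the surface: treated saturated under a head
#' boundary with h(0,t) >= 0 (ponding), unsaturated otherwise.  Block nz's
#' lower neighbour is itself.
#'
#' @inheritParams assemble_system
#' @param sat_tol saturation tolerance: theta >= theta_s - sat_tol counts
#'   as saturated
#' @return the new [flow_state()] at t + dt
#' @export
flux_update_step <- function(state, grid, models, bc, sink, dt,
                             kmean = c("arithmetic", "geometric"),
                             sat_tol = 1e-9) {
  kmean <- match.arg(kmean)
  nz <- grid$nz
  sys <- assemble_system(state, grid, models, bc, sink, dt, kmean)
  h_star <- thomas_solve(sys)
  if (any(!is.finite(h_star)))
    stop_step("non-finite heads from the tridiagonal solve")

  th_star <- vapply(seq_len(nz),
                    function(i) theta_of_h(models[[i]], h_star[i]),
                    numeric(1))
  K_new <- vapply(seq_len(nz),
                  function(i) K_of_theta(models[[i]], th_star[i]),
                  numeric(1))
  K_half_new <- numeric(nz + 1)
  K_half_new[2:nz] <- internode_K(K_new[1:(nz - 1)], K_new[2:nz], kmean)
  K_half_new[nz + 1] <- K_new[nz]
  K_half_new[1] <- if (bc$type == "head") {
    K_surf <- K_of_theta(models[[1]], theta_of_h(models[[1]], bc$value))
    internode_K(K_surf, K_new[1], kmean)
  } else 0
  J <- interface_fluxes(h_star, grid, K_half_new, bc)
  trial <- mass_balance_update(state$theta, J, sink, dt, grid)

  ts_vec <- vapply(models, function(m) m$theta_s, numeric(1))
  tr_vec <- vapply(models, function(m) m$theta_r, numeric(1))
  sat <- trial >= ts_vec - sat_tol
  surface_sat <- bc$type == "head" && bc$value >= 0

  h_new <- th_new <- numeric(nz)
  for (i in seq_len(nz)) {
    up <- if (i > 1) sat[i - 1] else surface_sat
    dn <- if (i < nz) sat[i + 1] else sat[i]
    if (!sat[i] && !up && !dn) {
      if (trial[i] <= tr_vec[i] + 1e-12)
        stop_step("trial theta %g below residual in block %d", trial[i], i)
      th_new[i] <- trial[i]
      h_new[i] <- h_of_theta(models[[i]], trial[i])
    } else {
      h_new[i] <- h_star[i]
      th_new[i] <- theta_of_h(models[[i]], h_star[i])
    }
  }
  if (any(!is.finite(h_new)) || any(!is.finite(th_new)))
    stop_step("non-finite state after flux-update step")
  out <- flow_state(t = state$t + dt, h = h_new, theta = th_new)
  attr(out, "fluxes") <- J
  attr(out, "h_star") <- h_star
  out
}
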
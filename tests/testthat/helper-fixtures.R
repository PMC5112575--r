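# shared fixtures built in code

loam <- function() vg_model(0.05, 0.45, alpha = 2, n = 1.8, K_s = 1e-6)

# the closed-form example soil used in hand-derived checks (n = 2, m = 1/2)
halfpow <- function() vg_model(0.05, 0.45, alpha = 2, n = 2, K_s = 1e-6)

small_column <- function(nz = 10, dz = 0.1, model = loam()) {
  grid <- flow_grid(nz, dz)
  profile <- soil_profile(list(model), depths = grid$z_max)
  list(grid = grid, profile = profile,
       models = block_models(profile, grid))
}

# hydrostatic (no-flow) head profile: dh/dz = 1 downward
hydrostatic_h <- function(grid, h_top = -100) h_top + (grid$z - grid$z[1])

# wide-open stress config: alpha = 1 over a broad head range
wet_cfg <- function(...) uptake_config(h1 = -0.001, h2 = -0.01, ...)

# dense linear solve of a tridiagonal system (oracle for thomas_solve)
dense_solve <- function(sys) {
  n <- length(sys$B)
  M <- diag(sys$B)
  if (n > 1) {
    M[cbind(2:n, 1:(n - 1))] <- sys$A[2:n]
    M[cbind(1:(n - 1), 2:n)] <- sys$C[1:(n - 1)]
  }
  solve(M, sys$D)
}

rand_tridiag <- function(n) {
  A <- c(0, runif(n - 1, -1, 1))
  C <- c(runif(n - 1, -1, 1), 0)
  B <- abs(A) + abs(C) + runif(n, 0.5, 2)   # diagonally dominant
  list(A = A, B = B, C = C, D = runif(n, -5, 5))
}
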
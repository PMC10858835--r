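#' Cahn-Hilliard-type energy of a density field
#'
#' Evaluates the Lyapunov functional of the moment-closure equation,
#' `E[u] = -int u (u + (sigma^2/2) u_xx) dx`, by Riemann sum on the periodic
#' grid with central second differences. Internally the equivalent
#' summation-by-parts form `-sum(u^2) dx + (sigma2/2) sum(u_x^2) dx` (forward
#' differences) is computed as a cross-check; the two agree to roundoff on a
#' periodic grid. Energy decreases along solutions of the closure equation,
#' and its local minima are the candidate asymptotic states. For snapshots of
#' the nonlocal model the kernel's second moment is used for `sigma2`, which
#' extends the functional to that model as a classification proxy.
#'
#' @param u Density field on `grid`.
#' @param sigma2 Kernel second moment (length^2).
#' @param grid A `"periodic_grid"`.
#' @return The scalar energy (density^2 * length units).
#' @examples
#' g <- build_grid(1, 0.01)
#' energy(rep(0.5, g$N), 0.1^2 / 3, g)   # -p^2/(2L) = -0.5 for p = L = 1
#' @export
energy <- function(u, sigma2, grid) {
  stopifnot(inherits(grid, "periodic_grid"))
  N <- grid$N
  dx <- grid$dx
  uxx <- (u[idx_p1(N)] - 2 * u + u[idx_m1(N)]) / dx^2
  e_direct <- -sum(u * (u + sigma2 / 2 * uxx)) * dx
  du <- (u[idx_p1(N)] - u) / dx
  e_parts <- -sum(u^2) * dx + sigma2 / 2 * sum(du^2) * dx
  scale <- max(1, abs(e_direct))
  if (abs(e_direct - e_parts) > 1e-9 * scale) {
    stop("energy cross-check failed: direct form ", e_direct,
         " vs summation-by-parts form ", e_parts)
  }
  e_direct
}

#' Energy dissipation rate along the moment-closure flow
#'
#' Evaluates `dE/dt = -2 gamma int u [ (u + (sigma^2/2) u_xx)_x ]^2 dx`,
#' which is nonpositive for nonnegative densities and vanishes exactly at
#' critical points of the energy. The inner derivative uses the periodic
#' central first difference.
#'
#' @param u Nonnegative density field (the sign argument needs `u >= 0`).
#' @param params A [model_params()] object (only `gamma` is used).
#' @param sigma2 Kernel second moment.
#' @param grid A `"periodic_grid"`.
#' @return The scalar dissipation rate (<= 0).
#' @export
dissipation_rate <- function(u, params, sigma2, grid) {
  stopifnot(inherits(grid, "periodic_grid"), inherits(params, "model_params"))
  if (any(u < 0)) {
    stop("dissipation_rate needs a nonnegative density (min u = ",
         min(u), ")")
  }
  N <- grid$N
  dx <- grid$dx
  v <- moment_closure(u, sigma2, grid)
  gx <- (v[idx_p1(N)] - v[idx_m1(N)]) / (2 * dx)
  -2 * params$gamma * sum(u * gx^2) * dx
}

#' Discrete mass of a density field
#'
#' @param u Density field on `grid`.
#' @param grid A `"periodic_grid"`.
#' @return `sum(u) * dx`, the total population size `p`.
#' @export
field_mass <- function(u, grid) {
  stopifnot(inherits(grid, "periodic_grid"))
  sum(u) * grid$dx
}
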
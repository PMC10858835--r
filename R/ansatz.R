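#' @name ansatz
#' @title Closed-form critical points of the aggregation energy
#'
#' @description
#' On any sub-arc where the density is positive, critical points of the
#' energy satisfy `u + (sigma^2/2) u'' = C`, whose solutions are
#' `C + A sin(sqrt(2) x/sigma) + B cos(sqrt(2) x/sigma)`. Gluing such arcs
#' to constant background yields continuously differentiable piecewise-cosine
#' profiles: compactly supported aggregation peaks of full width
#' `sqrt(2)*pi*sigma` sitting on a constant level. The constructors below
#' sample these profiles on a grid; the `energy_*_closed` functions give
#' their energies in closed form, against which the quadrature energy of the
#' sampled fields can be checked.
NULL

# wrap signed displacement onto (-L, L]
wrap_dist <- function(d, L) {
  ((d + L) %% (2 * L)) - L
}

# one cosine bump of amplitude parameter c centred at `centre`, zero outside
# its support of half-width pi*sigma/sqrt(2)
cos_bump <- function(x, centre, c_amp, sigma, L) {
  hw <- pi * sigma / sqrt(2)
  d <- wrap_dist(x - centre, L)
  ifelse(abs(d) < hw, c_amp * (1 + cos(sqrt(2) * d / sigma)), 0)
}

check_single_validity <- function(eps, p, L, sigma) {
  if (pi * sigma >= sqrt(2) * L) {
    stop("single-peak ansatz invalid: need pi*sigma < sqrt(2)*L, got ",
         "pi*sigma = ", pi * sigma, " vs sqrt(2)*L = ", sqrt(2) * L)
  }
  if (any(eps < 0 | eps > p / (2 * L) + 1e-12)) {
    stop("background level eps = ", eps[which.max(eps < 0 | eps > p / (2 * L) + 1e-12)],
         " outside the admissible interval ",
         "[0, p/(2L)] = [0, ", p / (2 * L), "]")
  }
}

#' Single-peak minimum-energy ansatz
#'
#' A compactly supported cosine peak of full width `sqrt(2)*pi*sigma` on a
#' constant background `eps`, with amplitude `c_eps = (p - 2*eps*L) /
#' (sqrt(2)*pi*sigma)` fixed by mass conservation, so the profile carries
#' total mass `p`. Valid whenever `pi*sigma < sqrt(2)*L`. The energy of this
#' family is an increasing function of `eps`, so `eps = 0` is its minimum.
#'
#' @param eps Background density in `[0, p/(2L)]`.
#' @param p Total mass.
#' @param L Half-domain length.
#' @param sigma Kernel width parameter (`sigma = delta/sqrt(3)` for a
#'   top-hat of half-width `delta`).
#' @param grid A `"periodic_grid"` to sample on.
#' @param centre Peak centre (default 0).
#' @return The sampled density field (numeric vector of length `grid$N`).
#' @examples
#' g <- build_grid(1, 0.01)
#' u <- single_peak(0, p = 1, L = 1, sigma = 0.1 / sqrt(3), grid = g)
#' max(u)   # peak height 2*c_0 ~ 7.80
#' @export
single_peak <- function(eps, p, L, sigma, grid, centre = 0) {
  stopifnot(inherits(grid, "periodic_grid"))
  check_single_validity(eps, p, L, sigma)
  c_eps <- (p - 2 * eps * L) / (sqrt(2) * pi * sigma)
  eps + cos_bump(grid$x, centre, c_eps, sigma, L)
}

#' Closed-form energy of the single-peak family
#'
#' `E(eps) = (2L/(pi*sigma))(pi*sigma - sqrt(2)L) eps^2
#'          + (2p/(pi*sigma))(sqrt(2)L - pi*sigma) eps - p^2/(sqrt(2)*pi*sigma)`,
#' a concave quadratic in `eps` with maximum at `eps = p/(2L)`, hence
#' increasing on the admissible interval `[0, p/(2L)]`.
#'
#' @inheritParams single_peak
#' @return The scalar energy.
#' @export
energy_single_closed <- function(eps, p, L, sigma) {
  check_single_validity(eps, p, L, sigma)
  ps <- pi * sigma
  (2 * L / ps) * (ps - sqrt(2) * L) * eps^2 +
    (2 * p / ps) * (sqrt(2) * L - ps) * eps -
    p^2 / (sqrt(2) * ps)
}

# peaks must have disjoint supports (x0 > pi*sigma/sqrt(2)); x0 = L/2 is the
# evenly-spaced (antipodal) configuration and is admissible
check_twin_geometry <- function(x0, L, sigma) {
  hw <- pi * sigma / sqrt(2)
  if (x0 <= hw || x0 > L / 2 + 1e-12) {
    stop("twin-peak half-separation x0 = ", x0, " outside the interval ",
         "(pi*sigma/sqrt(2), L/2] = (", hw, ", ", L / 2, "]")
  }
}

#' Equal twin-peak ansatz and its closed-form energy
#'
#' Two identical cosine peaks centred at `-x0` and `+x0` on background `eps`,
#' with amplitude `c_eps = (p - 2*L*eps)/(2*sqrt(2)*pi*sigma)` fixed by mass.
#' Needs disjoint supports, `x0 > pi*sigma/sqrt(2)`, evenly-spaceable
#' geometry `x0 < L/2`, and validity `sqrt(2)*pi*sigma < L`.
#'
#' @param eps Background density in `[0, p/(2L)]`.
#' @param x0 Half the distance between the two peak centres.
#' @inheritParams single_peak
#' @return `twin_equal()`: the sampled field; `energy_twin_equal_closed()`:
#'   the scalar energy
#'   `E(eps) = (sqrt(2)L/(pi*sigma))(sqrt(2)*pi*sigma - L) eps^2 +
#'    (sqrt(2)p/(pi*sigma))(L - sqrt(2)*pi*sigma) eps - p^2/(2*sqrt(2)*pi*sigma)`.
#' @export
twin_equal <- function(eps, x0, p, L, sigma, grid) {
  stopifnot(inherits(grid, "periodic_grid"))
  check_twin_validity(eps, p, L, sigma)
  check_twin_geometry(x0, L, sigma)
  c_eps <- (p - 2 * L * eps) / (2 * sqrt(2) * pi * sigma)
  eps + cos_bump(grid$x, -x0, c_eps, sigma, L) +
    cos_bump(grid$x, x0, c_eps, sigma, L)
}

check_twin_validity <- function(eps, p, L, sigma) {
  if (sqrt(2) * pi * sigma >= L) {
    stop("twin-peak ansatz invalid: need sqrt(2)*pi*sigma < L, got ",
         sqrt(2) * pi * sigma, " vs L = ", L)
  }
  if (any(eps < 0 | eps > p / (2 * L) + 1e-12)) {
    stop("background level eps outside [0, p/(2L)] = [0, ", p / (2 * L), "]")
  }
}

#' @rdname twin_equal
#' @export
energy_twin_equal_closed <- function(eps, p, L, sigma) {
  check_twin_validity(eps, p, L, sigma)
  ps <- pi * sigma
  (sqrt(2) * L / ps) * (sqrt(2) * ps - L) * eps^2 +
    (sqrt(2) * p / ps) * (L - sqrt(2) * ps) * eps -
    p^2 / (2 * sqrt(2) * ps)
}

#' Unequal twin-peak ansatz and its closed-form energy
#'
#' Two cosine peaks of different amplitudes on zero background: amplitude
#' `c_A` at `-x0` and `c_B` at `+x0`, with `c_A = p/(sqrt(2)*pi*sigma) - c_B`
#' fixed by mass conservation, so both must lie in
#' `[0, p/(sqrt(2)*pi*sigma)]`. The closed-form energy
#' `E(c_B) = -2*sqrt(2)*pi*sigma c_B^2 + 2 p c_B - p^2/(sqrt(2)*pi*sigma)`
#' is a concave quadratic whose *maximum* sits at the equal-peak point
#' `c_B = c_A`; its minima are the two boundary single-peak states, which is
#' why a smaller peak is expected to decay.
#'
#' @param c_B Amplitude parameter of the peak at `+x0` (start height of that
#'   peak is `2*c_B`).
#' @param x0 Half the distance between the peak centres.
#' @inheritParams single_peak
#' @return `twin_unequal()`: the sampled field; the closed energy otherwise.
#' @export
twin_unequal <- function(c_B, x0, p, L, sigma, grid) {
  stopifnot(inherits(grid, "periodic_grid"))
  c_A <- check_unequal_validity(c_B, p, sigma)
  check_twin_geometry(x0, L, sigma)
  cos_bump(grid$x, -x0, c_A, sigma, L) + cos_bump(grid$x, x0, c_B, sigma, L)
}

check_unequal_validity <- function(c_B, p, sigma) {
  cmax <- p / (sqrt(2) * pi * sigma)
  if (any(c_B < 0 | c_B > cmax + 1e-12)) {
    stop("c_B outside the admissible interval [0, p/(sqrt(2)*",
         "pi*sigma)] = [0, ", cmax, "]")
  }
  cmax - c_B
}

#' @rdname twin_unequal
#' @export
energy_twin_unequal_closed <- function(c_B, p, sigma) {
  check_unequal_validity(c_B, p, sigma)
  -2 * sqrt(2) * pi * sigma * c_B^2 + 2 * p * c_B - p^2 / (sqrt(2) * pi * sigma)
}

#' Minimise the closed-form energy over an ansatz family
#'
#' Vertex/boundary analysis of the closed-form quadratic over the family's
#' admissible parameter interval. All three families are concave quadratics,
#' so minima sit on the interval boundary; for the unequal twin family both
#' boundaries attain the same minimum (the two single-peak states) and both
#' are returned.
#'
#' @param family `"single"`, `"twin_equal"`, or `"twin_unequal"`.
#' @param p,L,sigma Family geometry as in [single_peak()].
#' @return A list with `family`, `parameter` (name of the free parameter),
#'   `argmin` (vector of minimising parameter values), `minimum` (the energy
#'   there), and `interval` (the admissible interval searched).
#' @export
minimize_family_energy <- function(family = c("single", "twin_equal",
                                              "twin_unequal"),
                                   p, L, sigma) {
  family <- match.arg(family)
  spec <- switch(family,
    single = list(f = function(e) energy_single_closed(e, p, L, sigma),
                  lo = 0, hi = p / (2 * L), parameter = "eps"),
    twin_equal = list(f = function(e) energy_twin_equal_closed(e, p, L, sigma),
                      lo = 0, hi = p / (2 * L), parameter = "eps"),
    twin_unequal = list(f = function(cb) energy_twin_unequal_closed(cb, p, sigma),
                        lo = 0, hi = p / (sqrt(2) * pi * sigma),
                        parameter = "c_B")
  )
  # candidates: interval ends plus the quadratic's vertex if interior
  cand <- c(spec$lo, spec$hi)
  h <- (spec$hi - spec$lo) / 2
  vals3 <- vapply(c(spec$lo, spec$lo + h, spec$hi), spec$f, numeric(1))
  a2 <- (vals3[1] - 2 * vals3[2] + vals3[3]) / (2 * h^2)  # quadratic coeff
  if (abs(a2) > 0) {
    a1 <- (vals3[3] - vals3[1]) / (2 * h)  # slope at midpoint
    vertex <- spec$lo + h - a1 / (2 * a2)
    if (vertex > spec$lo && vertex < spec$hi && a2 > 0) cand <- c(cand, vertex)
  }
  ev <- vapply(cand, spec$f, numeric(1))
  tol <- 1e-10 * max(1, abs(min(ev)))
  keep <- which(ev <= min(ev) + tol)
  list(family = family, parameter = spec$parameter,
       argmin = cand[keep], minimum = min(ev),
       interval = c(spec$lo, spec$hi))
}

#' Residual of the discrete critical-point condition
#'
#' At a critical point of the energy, `u (d/dx)(u + (sigma^2/2) u_xx) = 0`
#' everywhere. This diagnostic evaluates the square root of the dissipation
#' integrand, `sqrt(u) |(u + (sigma^2/2) u_xx)_x|`, with central differences,
#' and returns its supremum over the support mask. It vanishes to roundoff
#' on constant states, decreases as ~dx^2 under refinement on sampled
#' ansatz profiles (away from the support joins, where the profile is only
#' C^1), and is O(field scale) for generic non-steady states.
#'
#' @param u Density field on `grid`.
#' @param sigma2 Kernel second moment.
#' @param grid A `"periodic_grid"`.
#' @param support_mask Logical vector marking where to take the supremum;
#'   default `u > 1e-3 * max(u)`.
#' @return The scalar residual.
#' @export
critical_point_residual <- function(u, sigma2, grid, support_mask = NULL) {
  stopifnot(inherits(grid, "periodic_grid"))
  if (is.null(support_mask)) support_mask <- u > 1e-3 * max(u)
  if (!any(support_mask)) return(0)
  N <- grid$N
  v <- moment_closure(u, sigma2, grid)
  gx <- (v[idx_p1(N)] - v[idx_m1(N)]) / (2 * grid$dx)
  max(sqrt(pmax(u[support_mask], 0)) * abs(gx[support_mask]))
}

#' Serialise ansatz parameters to a JSON-ready list
#'
#' @param family Family name.
#' @param pars Named list of parameters (eps, x0, c_B, p, L, sigma, ...).
#' @return A named list suitable for `jsonlite::toJSON()`.
#' @export
ansatz_metadata <- function(family, pars) {
  c(list(family = family), pars)
}
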
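# shared fixtures: the reference configuration used across the suite
# (top-hat kernel delta = 0.1, so sigma = delta/sqrt(3))

std_sigma <- 0.1 / sqrt(3)

std_grid <- function(dx = 0.01, L = 1) build_grid(L, dx)

std_kernel <- function(grid, delta = 0.1) top_hat_kernel(delta, grid)

# run_simulation with the CFL advisory silenced (the reference parameters
# sit deliberately close to the advisory's conservative estimate)
quiet_run <- function(...) suppressWarnings(run_simulation(...))

# periodic half-domain window around x = centre
half_window <- function(centre, grid) peak_window(centre, grid)

# fabricate an "agg_trajectory" from an analytic space-time field, for
# oracle tests of the trajectory diagnostics
synthetic_trajectory <- function(times, field_fn, grid,
                                 sigma2 = std_sigma^2) {
  snaps <- vapply(times, function(t) field_fn(grid$x, t), numeric(grid$N))
  structure(
    list(times = times, snapshots = snaps, trace_times = times,
         mass_trace = colSums(snaps) * grid$dx,
         energy_trace = rep(NA_real_, length(times)),
         stop_reason = "horizon", t_final = max(times),
         steps_taken = NA_real_, u_final = snaps[, ncol(snaps)],
         scheme = "sg", grid = grid, params = model_params(),
         kernel_meta = list(kind = "synthetic", sigma2 = sigma2),
         sigma2 = sigma2, cfg = numerics_config(t_end = max(times))),
    class = "agg_trajectory"
  )
}
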
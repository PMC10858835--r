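#' Numerical settings for a forward-Euler run
#'
#' Defaults mirror the reference configuration used throughout the package's
#' experiments: `dt = 1e-5` with `dx = 0.01`, steady state declared when the
#' sup-norm change over 1000 consecutive steps falls below `1e-6`.
#'
#' @param t_end Simulation horizon (time units).
#' @param dt Time step.
#' @param record_every Snapshot interval in *simulated time* (so changing
#'   `dt` does not change the output schedule); default `t_end/100`.
#' @param trace_every Interval for the mass/energy traces; defaults to
#'   `record_every` but can be set as low as `dt` for per-step traces.
#' @param steady_check_lag Number of steps between compared states for
#'   steady-state detection (0 disables the check).
#' @param steady_tol Sup-norm tolerance declaring a steady state.
#' @param negativity_tol Densities below `-negativity_tol * max(u0)` abort
#'   the run (negativity indicates numerical failure, not physics).
#' @param seed Optional integer recorded in run metadata (the integrator
#'   itself is deterministic; the seed documents how the initial condition
#'   was drawn).
#' @return An object of class `"numerics_config"`.
#' @export
numerics_config <- function(t_end, dt = 1e-5, record_every = NULL,
                            trace_every = NULL, steady_check_lag = 1000L,
                            steady_tol = 1e-6, negativity_tol = 1e-8,
                            seed = NULL) {
  stopifnot(t_end > 0, dt > 0, steady_check_lag >= 0, steady_tol > 0,
            negativity_tol >= 0)
  if (is.null(record_every)) record_every <- t_end / 100
  if (is.null(trace_every)) trace_every <- record_every
  stopifnot(record_every > 0, trace_every > 0)
  structure(list(t_end = t_end, dt = dt, record_every = record_every,
                 trace_every = trace_every,
                 steady_check_lag = as.integer(steady_check_lag),
                 steady_tol = steady_tol, negativity_tol = negativity_tol,
                 seed = seed),
            class = "numerics_config")
}

#' One explicit Euler step
#'
#' @param u Current density field.
#' @param rhs Its time derivative (same length).
#' @param dt Time step.
#' @return `u + dt * rhs`. Non-finite values in the result raise a blow-up
#'   error.
#' @export
step_euler <- function(u, rhs, dt) {
  if (length(u) != length(rhs)) {
    stop("field and rhs lengths differ (", length(u), " vs ", length(rhs), ")")
  }
  out <- u + dt * rhs
  if (!all(is.finite(out))) stop("blow-up: non-finite values after Euler step")
  out
}

stop_reason_labels <- c("horizon", "steady", "blow-up", "negativity")

#' Run a model forward in time
#'
#' Advances an initial density by forward Euler (compiled inner loop) until
#' the horizon, a detected steady state, or a numerical failure. Snapshots
#' and mass/energy traces are recorded on a schedule of simulated time; the
#' final state is always recorded. A diffusive-CFL advisory (covering both
#' the second-order diffusion and the stiffness of the fourth-order closure
#' term) warns — but does not stop — when `dt` looks too large for the grid.
#'
#' @param u0 Nonnegative initial density on `grid`.
#' @param params A [model_params()] object selecting the model.
#' @param kernel_or_sigma2 A `"kernel_spec"` (for `"nonlocal"`/`"growth"`)
#'   or a scalar second moment `sigma2` (for `"local4th"`; a kernel is also
#'   accepted, its `sigma2` is used).
#' @param grid A `"periodic_grid"`.
#' @param cfg A [numerics_config()] object.
#' @param scheme Interface flux passed to the model right-hand side:
#'   `"sg"` (Scharfetter-Gummel, default) or `"central"`; see
#'   [rhs_nonlocal()].
#' @return An object of class `"agg_trajectory"`: list with `times`,
#'   `snapshots` (N x n_times matrix), `trace_times`, `mass_trace`,
#'   `energy_trace`, `stop_reason` (one of `"horizon"`, `"steady"`,
#'   `"blow-up"`, `"negativity"`), `t_final`, `u_final`, plus the `grid`,
#'   `params`, kernel metadata and `cfg` used.
#' @examples
#' g <- build_grid(1, 0.01)
#' k <- top_hat_kernel(0.1, g)
#' cfg <- numerics_config(t_end = 0.01, dt = 1e-5)
#' tr <- run_simulation(rep(0.5, g$N), model_params(), k, g, cfg)
#' tr$stop_reason   # "steady": the homogeneous state is a fixed point
#' @export
run_simulation <- function(u0, params, kernel_or_sigma2, grid, cfg,
                           scheme = c("sg", "central")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(params, "model_params"),
            inherits(grid, "periodic_grid"),
            inherits(cfg, "numerics_config"))
  if (length(u0) != grid$N) {
    stop("initial condition length ", length(u0),
         " does not match grid with N = ", grid$N)
  }
  if (!all(is.finite(u0))) stop("initial condition has non-finite values")
  if (min(u0) < 0) stop("initial condition must be nonnegative (min = ",
                        min(u0), ")")
  if (inherits(kernel_or_sigma2, "kernel_spec")) {
    kernel <- kernel_or_sigma2
    sigma2 <- kernel$sigma2
  } else if (is.numeric(kernel_or_sigma2) && length(kernel_or_sigma2) == 1L) {
    if (params$model != "local4th") {
      stop("a kernel_spec is required for model '", params$model, "'")
    }
    kernel <- NULL
    sigma2 <- kernel_or_sigma2
  } else {
    stop("kernel_or_sigma2 must be a kernel_spec or a scalar second moment")
  }
  if (params$model != "local4th" && is.null(kernel)) {
    stop("model '", params$model, "' needs a kernel")
  }

  cfl_advisory(u0, params, kernel, sigma2, grid, cfg)

  model_code <- match(params$model, c("nonlocal", "local4th", "growth")) - 1L
  scheme_code <- match(scheme, c("sg", "central")) - 1L
  koff <- if (is.null(kernel)) integer(0) else kernel$offsets
  kw <- if (is.null(kernel)) numeric(0) else kernel$weights
  nsteps <- ceiling(cfg$t_end / cfg$dt - 1e-9)
  res <- euler_run_cpp(
    as.numeric(u0), model_code, scheme_code,
    params$D, params$gamma, params$r, params$R,
    koff, kw, sigma2, grid$dx, cfg$dt, nsteps,
    round(cfg$record_every / cfg$dt), round(cfg$trace_every / cfg$dt),
    cfg$steady_check_lag, cfg$steady_tol,
    cfg$negativity_tol * max(u0)
  )
  structure(
    list(times = res$times, snapshots = res$snapshots,
         trace_times = res$trace_times, mass_trace = res$mass_trace,
         energy_trace = res$energy_trace,
         stop_reason = stop_reason_labels[res$stop_reason + 1L],
         t_final = res$t_final, steps_taken = res$steps_taken,
         u_final = res$snapshots[, ncol(res$snapshots)],
         scheme = scheme,
         grid = grid, params = params,
         kernel_meta = if (is.null(kernel)) list(kind = "none", sigma2 = sigma2)
                       else list(kind = kernel$kind, delta = kernel$delta,
                                 sigma2 = kernel$sigma2),
         sigma2 = sigma2, cfg = cfg),
    class = "agg_trajectory"
  )
}

# advisory stability estimate from the initial field: diffusive limit
# dt <= dx^2/(2D) and advective limit dt <= dx/max|a| with the drift
# a = gamma * v_x evaluated on u0 (v = K*u0 or its moment closure)
cfl_advisory <- function(u0, params, kernel, sigma2, grid, cfg) {
  dx <- grid$dx
  limits <- c()
  if (params$D > 0 && params$model != "local4th") {
    limits <- c(limits, dx^2 / (2 * params$D))
  }
  if (params$model == "local4th" || is.null(kernel)) {
    v <- moment_closure(u0, sigma2, grid)
    # fourth-order stiffness of the closure term (linearised about max u)
    k4 <- params$gamma * max(u0) * sigma2 / 2
    if (k4 > 0) limits <- c(limits, dx^4 / (8 * k4))
  } else {
    v <- convolve_periodic(u0, kernel, grid)
  }
  amax <- params$gamma * max(abs(diff(c(v, v[1]))) / dx)
  if (amax > 0) limits <- c(limits, dx / amax)
  if (length(limits) && cfg$dt > min(limits)) {
    warning("time step dt = ", cfg$dt, " exceeds the CFL estimate ",
            format(min(limits), digits = 3),
            " for this initial condition; the run may be unstable",
            call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.agg_trajectory <- function(x, ...) {
  cat("Trajectory (", x$params$model, "): ", ncol(x$snapshots),
      " snapshots to t = ", format(x$t_final),
      ", stop: ", x$stop_reason, "\n", sep = "")
  cat("  mass ", format(x$mass_trace[1]), " -> ",
      format(x$mass_trace[length(x$mass_trace)]),
      ";  energy ", format(x$energy_trace[1]), " -> ",
      format(x$energy_trace[length(x$energy_trace)]), "\n", sep = "")
  invisible(x)
}

#' Snapshot nearest a requested time
#'
#' @param traj An `"agg_trajectory"`.
#' @param t Requested time.
#' @return The recorded density field nearest `t`.
#' @export
snapshot_at <- function(traj, t) {
  stopifnot(inherits(traj, "agg_trajectory"))
  traj$snapshots[, which.min(abs(traj$times - t))]
}

#' Export a trajectory as long-format CSV
#'
#' Writes columns `time, x, u` (one row per node per snapshot), plus a JSON
#' metadata sidecar when `metadata_file` is given.
#'
#' @param traj An `"agg_trajectory"`.
#' @param file Output CSV path.
#' @param metadata_file Optional path for the JSON run metadata.
#' @return Invisibly, the paths written.
#' @export
write_trajectory_csv <- function(traj, file, metadata_file = NULL) {
  stopifnot(inherits(traj, "agg_trajectory"))
  nt <- length(traj$times)
  df <- data.frame(
    time = rep(traj$times, each = traj$grid$N),
    x = rep(traj$grid$x, nt),
    u = as.vector(traj$snapshots)
  )
  utils::write.csv(df, file, row.names = FALSE)
  paths <- file
  if (!is.null(metadata_file)) {
    jsonlite::write_json(trajectory_metadata(traj), metadata_file,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, metadata_file)
  }
  invisible(paths)
}

#' Run metadata as a JSON-ready list
#'
#' Captures everything needed to re-execute the run: model parameters, grid,
#' kernel, numerical settings, seed, and the stop reason.
#'
#' @param traj An `"agg_trajectory"`.
#' @return A named list.
#' @export
trajectory_metadata <- function(traj) {
  stopifnot(inherits(traj, "agg_trajectory"))
  list(
    model = traj$params$model,
    params = list(D = traj$params$D, gamma = traj$params$gamma,
                  r = traj$params$r, R = traj$params$R),
    grid = grid_metadata(traj$grid),
    kernel = traj$kernel_meta,
    numerics = list(dt = traj$cfg$dt, t_end = traj$cfg$t_end,
                    record_every = traj$cfg$record_every,
                    steady_check_lag = traj$cfg$steady_check_lag,
                    steady_tol = traj$cfg$steady_tol,
                    seed = traj$cfg$seed),
    stop_reason = traj$stop_reason,
    t_final = traj$t_final
  )
}
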
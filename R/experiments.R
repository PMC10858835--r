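#' Noisy perturbation of the homogeneous state
#'
#' The standard pattern-formation initial condition: the constant state
#' `p/(2L)` plus i.i.d. uniform noise in `[-amplitude, amplitude]` at each
#' node, rescaled multiplicatively so the quadrature mass is exactly `p`.
#' Deterministic under a fixed seed; the caller's RNG state is restored on
#' exit.
#'
#' @param p Total mass.
#' @param L Half-domain length.
#' @param grid A `"periodic_grid"`.
#' @param amplitude Noise half-width (must be below `p/(2L)` to keep the
#'   field positive).
#' @param seed Optional integer seed.
#' @return A nonnegative density field of mass exactly `p` (to roundoff).
#' @examples
#' g <- build_grid(1, 0.01)
#' u <- noise_ic(1, 1, g, seed = 1)
#' sum(u) * g$dx   # 1
#' @export
noise_ic <- function(p, L, grid, amplitude = 0.005, seed = NULL) {
  stopifnot(inherits(grid, "periodic_grid"), p > 0, L > 0, amplitude >= 0)
  base <- p / (2 * L)
  if (amplitude >= base) {
    stop("noise amplitude ", amplitude, " must be below the mean density ",
         "p/(2L) = ", base, " to keep the field positive")
  }
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old_seed)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
  }
  u <- base + stats::runif(grid$N, -amplitude, amplitude)
  u * p / (sum(u) * grid$dx)
}

#' Read a long-format trajectory CSV back into a trajectory object
#'
#' Inverse of [write_trajectory_csv()]: rebuilds an `"agg_trajectory"`
#' (snapshots, grid, mass and energy traces) from the `time, x, u` long
#' format, using the JSON metadata sidecar for the model parameters when
#' available.
#'
#' @param file CSV path written by [write_trajectory_csv()].
#' @param metadata_file Optional JSON sidecar path.
#' @return An `"agg_trajectory"` object (with `stop_reason` from the
#'   metadata, or `"horizon"` if unknown).
#' @export
read_trajectory_csv <- function(file, metadata_file = NULL) {
  df <- utils::read.csv(file)
  stopifnot(all(c("time", "x", "u") %in% names(df)))
  times <- sort(unique(df$time))
  xs <- sort(unique(df$x))
  dx <- xs[2] - xs[1]
  L <- -xs[1]
  grid <- build_grid(L, dx)
  snaps <- matrix(df$u[order(df$time, df$x)], nrow = length(xs))
  meta <- if (!is.null(metadata_file)) jsonlite::read_json(metadata_file,
                                                           simplifyVector = TRUE)
          else NULL
  sigma2 <- if (!is.null(meta)) meta$kernel$sigma2 else NA_real_
  params <- if (!is.null(meta)) {
    model_params(D = meta$params$D, gamma = meta$params$gamma,
                 r = meta$params$r, R = meta$params$R, model = meta$model)
  } else model_params()
  mass <- colSums(snaps) * dx
  e_tr <- if (is.finite(sigma2)) {
    vapply(seq_len(ncol(snaps)), function(k) energy(snaps[, k], sigma2, grid),
           numeric(1))
  } else rep(NA_real_, ncol(snaps))
  structure(
    list(times = times, snapshots = snaps, trace_times = times,
         mass_trace = mass, energy_trace = e_tr,
         stop_reason = if (!is.null(meta)) meta$stop_reason else "horizon",
         t_final = max(times), steps_taken = NA_real_,
         u_final = snaps[, ncol(snaps)], grid = grid, params = params,
         kernel_meta = if (!is.null(meta)) meta$kernel else
           list(kind = "unknown", sigma2 = sigma2),
         sigma2 = sigma2,
         cfg = numerics_config(t_end = max(times, 1e-6))),
    class = "agg_trajectory"
  )
}

experiment_names <- c("fig1", "fig2", "fig3", "fig4", "fig5", "rc_scan")

#' Reproduce a headline experiment
#'
#' Orchestrates the package's reference experiments at the standard
#' configuration `D = 1`, `gamma = 10`, `p = L = 1`, top-hat kernel
#' `delta = 0.1`, `dx = 0.01`, `dt = 1e-5`:
#'
#' * `fig1` — pattern formation from a noisy homogeneous state, then slow
#'   coarsening. The full decay of the smaller peak takes until `t ~ 460`;
#'   by default a scaled horizon (`t = 20 * scale`) demonstrates formation,
#'   and `full = TRUE` runs the whole thing.
#' * `fig2` — single-peak initial states with background
#'   `eps` in {0.1, 0.2, 0.3}: the background is absorbed into the peak;
#'   for `eps = 0.3` a transient secondary peak forms at the domain
#'   boundary and decays.
#' * `fig3` — equal twin peaks: persistence at `x0 = 0.5` (evenly spaced),
#'   merging for `x0 < 0.5`, and the merge-time trend over `x0`.
#' * `fig4` — unequal twin peaks: decay time of the smaller peak, its growth
#'   with `c_B` and decrease with `D`.
#' * `fig5` — logistic growth: smaller peak decays at `r = 0.23`, grows at
#'   `r = 0.24`.
#' * `rc_scan` — bisection bracket for the critical growth rate `r_c`.
#'
#' Every run writes its trajectory (long CSV), metadata (JSON), diagnostics
#' (JSON) and, optionally, a quick-look plot (PNG) into `outdir`; the
#' configuration (including `scale` and `seed`) is persisted so any bundle
#' can be re-executed.
#'
#' @param experiment One of `"fig1"`, `"fig2"`, `"fig3"`, `"fig4"`,
#'   `"fig5"`, `"rc_scan"`.
#' @param outdir Output directory (created if missing).
#' @param scale Horizon scale factor (< 1 shortens runs; recorded in the
#'   diagnostics as `scaled_down = TRUE`).
#' @param seed Seed for any stochastic initial condition.
#' @param dx,dt Grid spacing and time step.
#' @param full For `fig1`: run the full coarsening horizon (`t = 460`).
#' @param make_plots Write quick-look PNG plots.
#' @return Invisibly, a list of diagnostics per run (also written as JSON).
#' @export
reproduce <- function(experiment, outdir = "aggmeta-output", scale = 1,
                      seed = 1, dx = 0.01, dt = 1e-5, full = FALSE,
                      make_plots = FALSE) {
  if (!is.character(experiment) || length(experiment) != 1L ||
      !experiment %in% experiment_names) {
    stop("unknown experiment '", paste(experiment, collapse = ","),
         "'; available: ", paste(experiment_names, collapse = ", "))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- 1; L <- 1; delta <- 0.1
  grid <- build_grid(L, dx)
  kernel <- top_hat_kernel(delta, grid)
  sigma <- sqrt(kernel$sigma2)
  params <- model_params(D = 1, gamma = 10)
  config <- list(experiment = experiment, D = 1, gamma = 10, p = p, L = L,
                 delta = delta, dx = dx, dt = dt, scale = scale, seed = seed,
                 scaled_down = (scale < 1) || (experiment == "fig1" && !full))
  run_one <- function(tag, u0, pr, t_end, ksp = kernel) {
    cfg <- numerics_config(t_end = t_end, dt = dt,
                           record_every = max(dt, t_end / 50), seed = seed)
    tr <- run_simulation(u0, pr, ksp, grid, cfg)
    base <- file.path(outdir, paste0(experiment, "_", tag))
    write_trajectory_csv(tr, paste0(base, ".csv"), paste0(base, ".json"))
    if (make_plots) quicklook_plot(tr, paste0(base, ".png"))
    tr
  }
  out <- switch(experiment,
    fig1 = {
      u0 <- noise_ic(p, L, grid, amplitude = 0.005, seed = seed)
      t_end <- if (full) 460 else 20 * scale
      tr <- run_one("noise", u0, params, t_end)
      cl <- classify_state(tr$u_final, kernel$sigma2, p, L, grid)
      list(noise = list(stop_reason = tr$stop_reason, t_final = tr$t_final,
                        verdict = cl$verdict, n_peaks = cl$evidence$peak_count))
    },
    fig2 = {
      lapply(stats::setNames(c(0.1, 0.2, 0.3), paste0("eps", c(1, 2, 3))),
        function(eps) {
          u0 <- single_peak(eps, p, L, sigma, grid)
          tr <- run_one(paste0("eps", eps), u0, params, 10 * scale)
          cl <- classify_state(tr$u_final, kernel$sigma2, p, L, grid)
          res <- list(eps = eps, stop_reason = tr$stop_reason,
                      verdict = cl$verdict,
                      background = cl$evidence$background_mass_fraction,
                      width = cl$evidence$width)
          if (eps == 0.3) {
            res$secondary_decay_time <-
              as.numeric(decay_time(tr, window = peak_window(-L, grid)))
          }
          res
        })
    },
    fig3 = {
      u_even <- twin_equal(0.2, 0.5, p, L, sigma, grid)
      tr_even <- run_one("x0_0.5", u_even, params, 20 * scale)
      mt_even <- merge_time(tr_even, 0.5)
      scan <- lapply(c(0.25, 0.35, 0.45), function(x0) {
        u0 <- twin_equal(0.2, x0, p, L, sigma, grid)
        tr <- run_one(paste0("x0_", x0), u0, params, 60 * scale)
        list(x0 = x0, merge_time = as.numeric(merge_time(tr, x0)))
      })
      list(even = list(x0 = 0.5, merged = !is.na(mt_even)), scan = scan)
    },
    fig4 = {
      cb_scan <- lapply(c(0.5, 1.0, 1.5), function(cb) {
        u0 <- twin_unequal(cb, 0.5, p, L, sigma, grid)
        tr <- run_one(paste0("cB_", cb), u0, params, 25 * scale)
        list(c_B = cb, D = 1,
             decay_time = as.numeric(decay_time(tr, window = 0.5)))
      })
      d_scan <- lapply(c(0.5, 2), function(D) {
        pr <- model_params(D = D, gamma = 10)
        u0 <- twin_unequal(1.0, 0.5, p, L, sigma, grid)
        tr <- run_one(paste0("D_", D), u0, pr, 25 * scale)
        list(c_B = 1.0, D = D,
             decay_time = as.numeric(decay_time(tr, window = 0.5)))
      })
      list(c_B_scan = cb_scan, D_scan = d_scan)
    },
    fig5 = {
      lapply(stats::setNames(c(0.23, 0.24), c("r0.23", "r0.24")), function(r) {
        pr <- model_params(D = 1, gamma = 10, r = r, R = 5, model = "growth")
        u0 <- twin_unequal(1.0, 0.5, p, L, sigma, grid)
        tr <- run_one(paste0("r_", r), u0, pr, 10 * scale)
        wmax <- apply(tr$snapshots[peak_window(0.5, grid), ], 2, max)
        list(r = r, initial_height = wmax[1],
             final_height = wmax[length(wmax)],
             smaller_peak = if (wmax[length(wmax)] < wmax[1]) "decays"
                            else "grows")
      })
    },
    rc_scan = {
      pr <- model_params(D = 1, gamma = 10, r = 0.2, R = 5, model = "growth")
      u0 <- twin_unequal(1.0, 0.5, p, L, sigma, grid)
      cfg <- numerics_config(t_end = 10 * scale, dt = dt,
                             record_every = max(dt, 10 * scale / 50),
                             seed = seed)
      rc <- find_critical_growth_rate(u0, pr, kernel, grid, cfg,
                                      r_lo = 0.20, r_hi = 0.30,
                                      resolution = 0.01, window = 0.5)
      list(lower = rc$lower, upper = rc$upper,
           evaluations = rc$evaluations)
    }
  )
  bundle <- list(config = config, diagnostics = out)
  write_diagnostic_json(bundle,
                        file.path(outdir, paste0(experiment, "_diagnostics.json")))
  invisible(bundle)
}

quicklook_plot <- function(tr, file) {
  ok <- tryCatch({
    grDevices::png(file, width = 800, height = 500)
    on.exit(grDevices::dev.off())
    sel <- unique(round(seq(1, ncol(tr$snapshots), length.out = 6)))
    graphics::matplot(tr$grid$x, tr$snapshots[, sel], type = "l", lty = 1,
                      xlab = "x", ylab = "u",
                      main = paste0("t in [0, ", format(tr$t_final), "]"))
    TRUE
  }, error = function(e) FALSE)
  invisible(ok)
}
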
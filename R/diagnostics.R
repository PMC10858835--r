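#' Detect aggregation peaks in a density field
#'
#' Periodic-aware local maxima above a height threshold, with maxima closer
#' than `min_separation` merged (the highest wins). The default separation,
#' when `sigma` is supplied, is the ansatz support half-width
#' `pi*sigma/sqrt(2)`, so the two halves of one discrete peak are never
#' counted twice.
#'
#' @param u Density field on `grid`.
#' @param grid A `"periodic_grid"`.
#' @param height_threshold Minimum height for a maximum to count as a peak.
#' @param min_separation Merge radius (length units); defaults to
#'   `pi*sigma/sqrt(2)` if `sigma` is given, else `2*dx`.
#' @param sigma Optional kernel width parameter used for the default merge
#'   radius.
#' @return An object of class `"peak_set"`: list with `locations`, `heights`,
#'   `count`.
#' @export
find_peaks <- function(u, grid, height_threshold = 0.1,
                       min_separation = NULL, sigma = NULL) {
  stopifnot(inherits(grid, "periodic_grid"))
  if (!all(is.finite(u))) stop("density field has non-finite values")
  if (is.null(min_separation)) {
    min_separation <- if (is.null(sigma)) 2 * grid$dx else pi * sigma / sqrt(2)
  }
  N <- grid$N
  is_max <- u > u[idx_m1(N)] & u >= u[idx_p1(N)] & u > height_threshold
  cand <- which(is_max)
  if (length(cand) == 0L) {
    return(structure(list(locations = numeric(0), heights = numeric(0),
                          count = 0L), class = "peak_set"))
  }
  ord <- cand[order(u[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (length(kept) == 0L ||
        all(abs(wrap_dist(grid$x[i] - grid$x[kept], grid$L)) > min_separation)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  structure(list(locations = grid$x[kept], heights = u[kept],
                 count = length(kept)), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("Peaks:", x$count, "\n")
  if (x$count > 0) {
    print(data.frame(location = x$locations, height = x$heights))
  }
  invisible(x)
}

#' Time for twin peaks to merge
#'
#' Following the convention used in the coarsening experiments, the merge
#' time is the first recorded time at which the density evaluated at *both
#' initial peak-centre coordinates* `-x0` and `+x0` is strictly below the
#' threshold: as two peaks migrate toward coalescence the density at the
#' original centres falls. (The alternative reading — density at the
#' midpoint between the peaks — rises during merging and can never drop
#' below the threshold; the interpretation used is recorded in the result's
#' attributes.)
#'
#' @param traj An `"agg_trajectory"` started from a twin-peak state with
#'   known half-separation `x0`.
#' @param x0 Half the distance between the initial peak centres.
#' @param threshold Density threshold (strict inequality).
#' @return The merge time (numeric), or `NA` if the peaks have not merged
#'   within the recorded horizon. Attributes `interpretation`, `threshold`
#'   and `nodes` record the measurement convention.
#' @export
merge_time <- function(traj, x0, threshold = 0.1) {
  stopifnot(inherits(traj, "agg_trajectory"))
  if (length(traj$times) < 2L) {
    warning("trajectory has fewer than 2 snapshots; merge time indeterminate")
  }
  g <- traj$grid
  i_minus <- which.min(abs(g$x - (-x0)))
  i_plus <- which.min(abs(g$x - x0))
  below <- traj$snapshots[i_minus, ] < threshold &
           traj$snapshots[i_plus, ] < threshold
  t_merge <- if (any(below)) traj$times[which(below)[1]] else NA_real_
  structure(t_merge,
            interpretation = "density at the two initial peak centres",
            threshold = threshold, nodes = c(g$x[i_minus], g$x[i_plus]))
}

#' Logical mask for a periodic sub-arc window
#'
#' @param centre Window centre (periodic coordinate).
#' @param grid A `"periodic_grid"`.
#' @param halfwidth Window half-width; default `L/2` (half the domain).
#' @return Logical vector over the grid nodes.
#' @export
peak_window <- function(centre, grid, halfwidth = grid$L / 2) {
  stopifnot(inherits(grid, "periodic_grid"))
  abs(wrap_dist(grid$x - centre, grid$L)) <= halfwidth + 1e-12
}

#' Time for a peak to decay
#'
#' First recorded time at which the maximum density over a fixed window
#' falls below the threshold. The default window is half the domain centred
#' on the decaying peak's initial centre, which is reproducible because the
#' peaks in this regime do not migrate far before decaying.
#'
#' @param traj An `"agg_trajectory"`.
#' @param window Logical node mask (see [peak_window()]) or a window centre
#'   (scalar), in which case a half-domain window is used.
#' @param threshold Density threshold (strict inequality).
#' @return The decay time (numeric; 0 if already below the threshold at the
#'   first snapshot), or `NA` if the windowed maximum never falls below the
#'   threshold within the recorded horizon. Attribute `window_max` carries
#'   the windowed-maximum trace.
#' @export
decay_time <- function(traj, window, threshold = 0.1) {
  stopifnot(inherits(traj, "agg_trajectory"))
  if (is.numeric(window) && length(window) == 1L) {
    window <- peak_window(window, traj$grid)
  }
  stopifnot(is.logical(window), length(window) == traj$grid$N, any(window))
  wmax <- apply(traj$snapshots[window, , drop = FALSE], 2, max)
  below <- wmax < threshold
  t_decay <- if (any(below)) traj$times[which(below)[1]] else NA_real_
  structure(t_decay, threshold = threshold, window_max = wmax)
}

# width of the (single) region where u exceeds rel_threshold * max(u)
peak_support_width <- function(u, grid, rel_threshold = 0.01) {
  sum(u > rel_threshold * max(u)) * grid$dx
}

#' Classify a state as candidate-asymptotic or transient
#'
#' Operationalises the energy-minimisation hypothesis: states matching a
#' local minimum of the energy over the piecewise-cosine families are
#' candidate asymptotic states; everything else patterned is a transient.
#' The decision procedure is
#'
#' 1. detect peaks above `height_threshold`;
#' 2. no peaks (constant-like state): `"indeterminate"` — whether patterns
#'    would form from it is not assessed here;
#' 3. one peak: `"candidate-asymptotic"` (matched to the compactly
#'    supported single-peak minimiser) if the background mass fraction is
#'    below 1% and the support width is within 25% of `sqrt(2)*pi*sigma`,
#'    else `"transient"`;
#' 4. two or more peaks: `"transient"` unless the heights agree within 1%
#'    *and* the spacing is even within 1% of `2L/count` — that knife-edge
#'    case (identical, evenly-spaced peaks) is `"candidate-asymptotic"` and
#'    flagged.
#'
#' The energy gap to the single-peak minimum is always reported as evidence.
#'
#' @param u Nonnegative density field with mass approximately `p`.
#' @param sigma2 Kernel second moment.
#' @param p Total mass.
#' @param L Half-domain length.
#' @param grid A `"periodic_grid"`.
#' @param height_threshold Peak detection threshold.
#' @return An object of class `"classification_result"`: list with
#'   `verdict`, `matched_template`, `evidence` (energy gap, peak count,
#'   height asymmetry, spacing deviation, background mass fraction, width),
#'   and `flags`.
#' @export
classify_state <- function(u, sigma2, p, L, grid, height_threshold = 0.1) {
  stopifnot(inherits(grid, "periodic_grid"))
  if (min(u) < 0) stop("classification needs a nonnegative density (min = ",
                       min(u), ")")
  sigma <- sqrt(sigma2)
  target_width <- sqrt(2) * pi * sigma
  peaks <- find_peaks(u, grid, height_threshold, sigma = sigma)
  e_gap <- energy(u, sigma2, grid) - energy_single_closed(0, p, L, sigma)
  evidence <- list(energy_gap = e_gap, peak_count = peaks$count,
                   height_asymmetry = NA_real_, spacing_deviation = NA_real_,
                   background_mass_fraction = NA_real_, width = NA_real_)
  flags <- character(0)
  template <- NULL

  if (peaks$count == 0L) {
    verdict <- "indeterminate"
    flags <- "no peaks above threshold; pattern-forming ability not assessed"
  } else if (peaks$count == 1L) {
    outside <- !peak_window(peaks$locations, grid, halfwidth = target_width)
    evidence$background_mass_fraction <- sum(u[outside]) * grid$dx / p
    evidence$width <- peak_support_width(u, grid)
    ok_bg <- evidence$background_mass_fraction < 0.01
    ok_width <- abs(evidence$width - target_width) / target_width < 0.25
    if (ok_bg && ok_width) {
      verdict <- "candidate-asymptotic"
      template <- list(family = "single", eps = 0, p = p, L = L,
                       sigma = sigma, centre = peaks$locations)
    } else {
      verdict <- "transient"
      if (!ok_bg) flags <- c(flags, "background mass not absorbed")
      if (!ok_width) flags <- c(flags, "support width off the minimiser's")
    }
  } else {
    evidence$height_asymmetry <- max(peaks$heights) / min(peaks$heights) - 1
    gaps <- diff(c(peaks$locations, peaks$locations[1] + 2 * L))
    even_gap <- 2 * L / peaks$count
    evidence$spacing_deviation <- max(abs(gaps - even_gap)) / even_gap
    outside <- rep(TRUE, grid$N)
    for (loc in peaks$locations) {
      outside <- outside & !peak_window(loc, grid, halfwidth = target_width)
    }
    evidence$background_mass_fraction <-
      if (any(outside)) sum(u[outside]) * grid$dx / p else 0
    if (evidence$height_asymmetry < 0.01 &&
        evidence$spacing_deviation < 0.01 &&
        evidence$background_mass_fraction < 0.01) {
      verdict <- "candidate-asymptotic"
      flags <- "knife-edge: identical evenly-spaced peaks (unstable to asymmetry)"
      template <- list(family = if (peaks$count == 2L) "twin_equal" else
                         "multi_equal",
                       eps = 0, p = p, L = L, sigma = sigma,
                       centres = peaks$locations)
    } else {
      verdict <- "transient"
      if (evidence$height_asymmetry >= 0.01) {
        flags <- c(flags, "unequal peak heights: smaller peak expected to decay")
      }
      if (evidence$spacing_deviation >= 0.01) {
        flags <- c(flags, "uneven spacing: peaks expected to migrate and merge")
      }
      if (evidence$background_mass_fraction >= 0.01) {
        flags <- c(flags, "background mass not absorbed")
      }
    }
  }
  structure(list(verdict = verdict, matched_template = template,
                 evidence = evidence, flags = flags),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("Verdict:", x$verdict, "\n")
  cat("  peaks:", x$evidence$peak_count,
      " energy gap to single-peak minimum:",
      format(x$evidence$energy_gap, digits = 4), "\n")
  for (f in x$flags) cat("  -", f, "\n")
  invisible(x)
}

#' Find the critical logistic growth rate by grid bisection
#'
#' Under logistic growth there is a critical rate `r_c` above which the
#' smaller of two unequal peaks persists (grows) instead of decaying.
#' This routine classifies the smaller peak as decaying or growing at the
#' horizon for rates on a grid of spacing `resolution`, and bisects the
#' grid index to return the bracketing pair `(r_decay, r_grow)` with
#' `r_grow - r_decay = resolution`. A run "decays" when the windowed maximum
#' at the horizon is below its initial value and monotonically declining
#' over the last 20% of the horizon; it "grows" otherwise when above its
#' initial value.
#'
#' @param ic Initial density (typically an unequal twin-peak ansatz).
#' @param params A [model_params()] with `model = "growth"`; its `r` is
#'   overridden during the scan.
#' @param kernel A `"kernel_spec"`.
#' @param grid A `"periodic_grid"`.
#' @param cfg A [numerics_config()]; `cfg$t_end` is the classification
#'   horizon.
#' @param r_lo,r_hi Bracket endpoints: the peak must decay at `r_lo` and
#'   grow at `r_hi` (checked first; a violated or degenerate bracket is an
#'   error naming both endpoint classifications).
#' @param resolution Grid spacing for `r` (also the width of the returned
#'   bracket).
#' @param window Node mask or centre for the smaller peak's window
#'   (default: half-domain centred on the highest initial peak's mirror —
#'   supply explicitly for clarity).
#' @param threshold Decay threshold handed to the trend classification.
#' @return A list with `lower` and `upper` (the bracket `[r_decay, r_grow]`),
#'   and `evaluations`, a data frame of every `(r, verdict)` computed.
#' @export
find_critical_growth_rate <- function(ic, params, kernel, grid, cfg,
                                      r_lo, r_hi, resolution = 0.01,
                                      window, threshold = 0.1) {
  stopifnot(inherits(params, "model_params"), inherits(cfg, "numerics_config"))
  if (r_hi <= r_lo) {
    stop("degenerate bracket: r_lo = ", r_lo, ", r_hi = ", r_hi)
  }
  K <- round((r_hi - r_lo) / resolution)
  if (abs(r_lo + K * resolution - r_hi) > 1e-9) {
    stop("bracket [", r_lo, ", ", r_hi, "] is not a whole number of ",
         "resolution steps (", resolution, ")")
  }
  if (is.numeric(window) && length(window) == 1L) {
    window <- peak_window(window, grid)
  }
  stopifnot(is.logical(window), length(window) == grid$N)
  wmax0 <- max(ic[window])

  classify_r <- function(r) {
    pr <- model_params(D = params$D, gamma = params$gamma, r = r,
                       R = params$R, model = "growth")
    tr <- run_simulation(ic, pr, kernel, grid, cfg)
    wmax <- apply(tr$snapshots[window, , drop = FALSE], 2, max)
    tail_ix <- which(tr$times >= 0.8 * tr$t_final)
    declining <- all(diff(wmax[tail_ix]) <= 1e-9 * max(wmax))
    final <- wmax[length(wmax)]
    if (final < wmax0 && declining) "decays" else "grows"
  }

  verdicts <- rep(NA_character_, K + 1)
  eval_k <- function(k) {
    if (is.na(verdicts[k + 1])) verdicts[k + 1] <<- classify_r(r_lo + k * resolution)
    verdicts[k + 1]
  }
  v_lo <- eval_k(0)
  v_hi <- eval_k(K)
  if (v_lo != "decays" || v_hi != "grows") {
    stop("invalid bracket: peak '", v_lo, "' at r_lo = ", r_lo,
         " and '", v_hi, "' at r_hi = ", r_hi,
         " (need decays at r_lo, grows at r_hi)")
  }
  lo <- 0L
  hi <- K
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (eval_k(mid) == "decays") lo <- mid else hi <- mid
  }
  done <- which(!is.na(verdicts))
  list(lower = r_lo + lo * resolution, upper = r_lo + hi * resolution,
       evaluations = data.frame(r = r_lo + (done - 1) * resolution,
                                verdict = verdicts[done]))
}

#' Write a diagnostic record as JSON
#'
#' @param record A named list (inputs, thresholds, verdicts, flags).
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_diagnostic_json <- function(record, file) {
  jsonlite::write_json(record, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
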
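# plain cosine bump of half-width w and height h, periodic distance
test_bump <- function(x, centre, h, w, L = 1) {
  d <- ((x - centre + L) %% (2 * L)) - L
  ifelse(abs(d) < w, h / 2 * (1 + cos(pi * d / w)), 0)
}

test_that("find_peaks detects, thresholds, and merges periodic maxima", {
  g <- std_grid()
  expect_equal(find_peaks(rep(0.5, g$N), g)$count, 0L)
  u <- twin_unequal(1.5, 0.3, 1, 1, std_sigma, g)
  pk <- find_peaks(u, g, height_threshold = 0.1, sigma = std_sigma)
  expect_equal(pk$count, 2L)
  expect_equal(sort(pk$locations), c(-0.3, 0.3), tolerance = 1e-9)
  expect_gt(max(pk$heights), min(pk$heights))   # unequal heights
  # maxima below threshold do not count
  expect_equal(find_peaks(0.05 * u / max(u), g)$count, 0L)
  # two maxima closer than min_separation merge, highest wins
  u2 <- test_bump(g$x, 0, 2, 0.1) + test_bump(g$x, 0.12, 1, 0.1)
  pk2 <- find_peaks(u2, g, min_separation = 0.3)
  expect_equal(pk2$count, 1L)
  expect_equal(pk2$locations, 0, tolerance = 0.02)
  # peak at the domain seam x = -L is found once
  u3 <- test_bump(g$x, -1, 2, 0.15)
  pk3 <- find_peaks(u3, g, min_separation = 0.3)
  expect_equal(pk3$count, 1L)
})

test_that("merge time matches the first-passage of translating bumps", {
  g <- std_grid()
  x0 <- 0.5; h <- 2; w <- 0.2; v <- 0.05
  traj <- synthetic_trajectory(seq(0, 5, by = 0.01), function(x, t) {
    test_bump(x, -x0 + v * t, h, w) + test_bump(x, x0 - v * t, h, w)
  }, g)
  # density at the initial centres: h/2 (1 + cos(pi v t / w)) < 0.1
  t_star <- acos(2 * 0.1 / h - 1) * w / (pi * v)
  mt <- merge_time(traj, x0, threshold = 0.1)
  expect_false(is.na(mt))
  expect_lt(abs(as.numeric(mt) - t_star), 0.011)
  expect_match(attr(mt, "interpretation"), "initial peak centres")
})

test_that("merge time uses a strict threshold and reports non-merging", {
  g <- std_grid()
  traj_const <- synthetic_trajectory(seq(0, 1, by = 0.1),
                                     function(x, t) rep(0.1, length(x)), g)
  expect_true(is.na(merge_time(traj_const, 0.5, threshold = 0.1)))
  traj_below <- synthetic_trajectory(seq(0, 1, by = 0.1),
                                     function(x, t) rep(0.0999, length(x)), g)
  expect_equal(as.numeric(merge_time(traj_below, 0.5)), 0)
})

test_that("decay time matches a closed-form exponential decay", {
  g <- std_grid()
  traj <- synthetic_trajectory(seq(0, 5, by = 0.005), function(x, t) {
    2 * exp(-t) * test_bump(x, 0.5, 1, 0.15)
  }, g)
  dt_meas <- decay_time(traj, window = 0.5, threshold = 0.1)
  expect_lt(abs(as.numeric(dt_meas) - log(20)), 0.006)
  # already below threshold at t = 0
  traj0 <- synthetic_trajectory(c(0, 1), function(x, t) rep(0.01, length(x)), g)
  expect_equal(as.numeric(decay_time(traj0, window = 0.5)), 0)
  # never decays
  traj_up <- synthetic_trajectory(c(0, 1), function(x, t) rep(1, length(x)), g)
  expect_true(is.na(decay_time(traj_up, window = 0.5)))
})

test_that("peak_window wraps around the periodic seam", {
  g <- std_grid()
  w <- peak_window(-1, g, halfwidth = 0.25)
  expect_true(all(w[abs(g$x + 1) < 0.24]))
  expect_true(all(w[g$x > 0.76]))       # wraps past x = +1
  expect_false(any(w[abs(g$x) < 0.5]))
})

test_that("classification follows the energy-minimisation rules", {
  g <- std_grid()
  s2 <- std_sigma^2
  # the compact single-peak minimiser is candidate-asymptotic
  cl1 <- classify_state(single_peak(0, 1, 1, std_sigma, g), s2, 1, 1, g)
  expect_equal(cl1$verdict, "candidate-asymptotic")
  expect_equal(cl1$matched_template$family, "single")
  # unequal twins are transient with the asymmetry recorded
  cl2 <- classify_state(twin_unequal(1.5, 0.3, 1, 1, std_sigma, g),
                        s2, 1, 1, g)
  expect_equal(cl2$verdict, "transient")
  expect_gt(cl2$evidence$height_asymmetry, 0.01)
  # equal evenly-spaced twins on an unabsorbed background are transient
  cl3 <- classify_state(twin_equal(0.2, 0.5, 1, 1, std_sigma, g),
                        s2, 1, 1, g)
  expect_equal(cl3$verdict, "transient")
  expect_gt(cl3$evidence$background_mass_fraction, 0.01)
  # ... but with the background absorbed they are the knife-edge case
  cl4 <- classify_state(twin_equal(0, 0.5, 1, 1, std_sigma, g), s2, 1, 1, g)
  expect_equal(cl4$verdict, "candidate-asymptotic")
  expect_true(any(grepl("knife-edge", cl4$flags)))
  # single-peak background not absorbed -> transient
  cl5 <- classify_state(single_peak(0.2, 1, 1, std_sigma, g), s2, 1, 1, g)
  expect_equal(cl5$verdict, "transient")
  # verdicts of transient states always carry evidence flags
  for (cl in list(cl2, cl3, cl5)) expect_gt(length(cl$flags), 0)
  expect_error(classify_state(c(-1, rep(1, g$N - 1)), s2, 1, 1, g),
               "nonnegative")
})

test_that("energy-family minimisers classify as their own templates", {
  g <- std_grid()
  s2 <- std_sigma^2
  ms <- minimize_family_energy("single", 1, 1, std_sigma)
  u_min <- single_peak(ms$argmin[1], 1, 1, std_sigma, g)
  expect_equal(classify_state(u_min, s2, 1, 1, g)$verdict,
               "candidate-asymptotic")
  # any markedly unequal twin sample is transient
  cmax <- 1 / (sqrt(2) * pi * std_sigma)
  for (cb in c(0.5, 1.2, 3)) {
    if (abs(cmax - 2 * cb) > 0.05 * cmax) {
      expect_equal(classify_state(twin_unequal(cb, 0.35, 1, 1, std_sigma, g),
                                  s2, 1, 1, g)$verdict, "transient")
    }
  }
})

test_that("critical growth-rate bisection brackets a real transition", {
  # diffusion-dominated regime: without growth the off-centre peak spreads
  # away (decays); with strong logistic growth the window fills toward the
  # carrying capacity (grows) -- so a transition exists in between
  g <- build_grid(1, 0.02)
  k <- top_hat_kernel(0.1, g)
  u0 <- twin_unequal(1.0, 0.5, 1, 1, std_sigma, g)
  pr <- model_params(D = 1, gamma = 0, r = 0, R = 5, model = "growth")
  cfg <- numerics_config(t_end = 1, dt = 2e-5, record_every = 0.05,
                         steady_check_lag = 0)
  rc <- find_critical_growth_rate(u0, pr, k, g, cfg, r_lo = 0, r_hi = 8,
                                  resolution = 1, window = 0.5)
  expect_equal(rc$upper - rc$lower, 1)
  expect_true(all(c("decays", "grows") %in% rc$evaluations$verdict))
  expect_true(rc$lower >= 0 && rc$upper <= 8)
  # degenerate and invalid brackets are rejected with diagnoses
  expect_error(find_critical_growth_rate(u0, pr, k, g, cfg, 1, 1,
                                         resolution = 1, window = 0.5),
               "degenerate")
  expect_error(find_critical_growth_rate(u0, pr, k, g, cfg, 6, 8,
                                         resolution = 1, window = 0.5),
               "invalid bracket")
})

test_that("diagnostic records serialise to JSON", {
  f <- tempfile(fileext = ".json")
  write_diagnostic_json(list(verdict = "transient", threshold = 0.1), f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$verdict, "transient")
  expect_equal(back$threshold, 0.1)
})
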
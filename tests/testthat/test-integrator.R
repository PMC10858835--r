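test_that("step_euler is exact linear stepping with blow-up detection", {
  expect_identical(step_euler(rep(0.5, 8), rep(1, 8), 1e-5), rep(0.50001, 8))
  u <- runif(16)
  expect_identical(step_euler(u, rep(0, 16), 0.1), u)
  expect_error(step_euler(c(1, 2), c(Inf, 0), 1e-3), "blow-up")
  expect_error(step_euler(rep(1, 4), rep(1, 5), 1e-3), "lengths differ")
  # conservative rhs keeps mass exactly
  rhs <- rnorm(32)
  rhs <- rhs - mean(rhs)
  expect_lt(abs(sum(step_euler(rep(1, 32), rhs, 1e-4)) - 32), 1e-12)
})

test_that("numerics_config applies the reference defaults", {
  cfg <- numerics_config(t_end = 1)
  expect_equal(cfg$dt, 1e-5)
  expect_equal(cfg$steady_check_lag, 1000L)
  expect_equal(cfg$steady_tol, 1e-6)
  expect_error(numerics_config(t_end = -1))
  expect_error(numerics_config(t_end = 1, dt = 0))
})

test_that("compiled stepping matches R-level stepping of the same rhs", {
  g <- std_grid()
  k <- std_kernel(g)
  pr <- model_params(D = 1, gamma = 10)
  u0 <- single_peak(0.1, 1, 1, std_sigma, g)
  nst <- 200
  cfg <- numerics_config(t_end = nst * 1e-5, dt = 1e-5,
                         record_every = nst * 1e-5, steady_check_lag = 0)
  tr <- quiet_run(u0, pr, k, g, cfg)
  u <- u0
  for (s in seq_len(nst)) u <- u + 1e-5 * rhs_nonlocal(u, pr, k, g)
  expect_lt(max(abs(u - tr$u_final)), 1e-10)
})

test_that("constant initial data is declared steady at the first check", {
  g <- std_grid()
  k <- std_kernel(g)
  cfg <- numerics_config(t_end = 1, dt = 1e-5)
  tr <- run_simulation(rep(0.5, g$N), model_params(), k, g, cfg)
  expect_equal(tr$stop_reason, "steady")
  expect_equal(tr$t_final, 0.01)   # 1000-step lag
  expect_true(all(abs(tr$snapshots - 0.5) < 1e-12))
})

test_that("mass is conserved and symmetry preserved along nonlocal runs", {
  g <- std_grid()
  k <- std_kernel(g)
  mirror <- function(z) z[c(1, g$N:2)]
  # symmetrise the sampled profile exactly: the aggregation instability
  # amplifies even last-bit asymmetry, so the invariant is about the
  # scheme (which is mirror-exact), not about sampling roundoff
  u0 <- single_peak(0.1, 1, 1, std_sigma, g)
  u0 <- (u0 + mirror(u0)) / 2
  cfg <- numerics_config(t_end = 0.1, dt = 1e-5, record_every = 0.02,
                         trace_every = 0.001, steady_check_lag = 0)
  tr <- quiet_run(u0, model_params(), k, g, cfg)
  expect_equal(tr$stop_reason, "horizon")
  p0 <- sum(u0) * g$dx
  expect_lt(max(abs(tr$mass_trace - p0)), 1e-10)
  expect_lt(max(abs(tr$u_final - mirror(tr$u_final))), 1e-9)
  # snapshots recorded on the simulated-time schedule, final always present
  expect_equal(tr$times, seq(0, 0.1, by = 0.02))
})

test_that("the Cahn-Hilliard energy decreases along closure trajectories", {
  g <- std_grid()
  k <- std_kernel(g)
  u0 <- noise_ic(1, 1, g, seed = 8)
  cfg <- numerics_config(t_end = 2e4 * 5e-8, dt = 5e-8,
                         record_every = 1e3 * 5e-8, trace_every = 5e-8,
                         steady_check_lag = 0)
  tr <- quiet_run(u0, model_params(model = "local4th"), k$sigma2, g, cfg)
  expect_equal(tr$stop_reason, "horizon")
  expect_lt(max(diff(tr$energy_trace)), 1e-8)
})

test_that("stiff explicit steps abort with a diagnosed failure", {
  g <- std_grid()
  k <- std_kernel(g)
  # the closure equation is fourth-order: dt = 1e-5 is far beyond its
  # explicit stability limit and the run must flag itself, not continue
  cfg <- numerics_config(t_end = 0.01, dt = 1e-5, steady_check_lag = 0)
  tr <- quiet_run(noise_ic(1, 1, g, seed = 4),
                  model_params(model = "local4th"), k$sigma2, g, cfg)
  expect_true(tr$stop_reason %in% c("blow-up", "negativity"))
  expect_lt(tr$t_final, 0.01)
  # the central flux undershoots at sharp aggregation fronts -> negativity
  tr2 <- quiet_run(single_peak(0.1, 1, 1, std_sigma, g), model_params(),
                   k, g, numerics_config(t_end = 0.05, dt = 1e-5,
                                         steady_check_lag = 0),
                   scheme = "central")
  expect_equal(tr2$stop_reason, "negativity")
})

test_that("the CFL advisory warns on oversized steps", {
  g <- std_grid()
  k <- std_kernel(g)
  # the fourth-order closure term limits explicit steps to ~dx^4 scale,
  # far below the reference dt of the second-order models
  expect_warning(
    run_simulation(rep(0.5, g$N), model_params(model = "local4th"),
                   k$sigma2, g,
                   numerics_config(t_end = 2e-5, dt = 1e-5,
                                   steady_check_lag = 0)),
    "CFL")
})

test_that("refinement in dt is first order, in dx about second order", {
  # gentle advective regime keeps both schemes in their smooth range
  sol_dt <- function(dt) {
    g <- build_grid(1, 0.01)
    k <- top_hat_kernel(0.1, g)
    cfg <- numerics_config(t_end = 0.01, dt = dt, record_every = 0.01,
                           steady_check_lag = 0)
    quiet_run(0.5 + 0.1 * cos(pi * g$x), model_params(D = 1, gamma = 1),
              k, g, cfg)$u_final
  }
  u1 <- sol_dt(4e-5); u2 <- sol_dt(2e-5); u3 <- sol_dt(1e-5)
  r_dt <- max(abs(u1 - u2)) / max(abs(u2 - u3))
  expect_gt(r_dt, 1.5)
  expect_lt(r_dt, 3)

  # dx halving: compare on shared coarse nodes, with dt small enough that
  # temporal error does not mask the spatial order; dx values divide the
  # kernel half-width so its sampling stays consistent across levels
  sol_dx <- function(dx) {
    g <- build_grid(1, dx)
    k <- top_hat_kernel(0.1, g)
    cfg <- numerics_config(t_end = 0.01, dt = 2e-6, record_every = 0.01,
                           steady_check_lag = 0)
    list(u = quiet_run(0.5 + 0.1 * cos(pi * g$x),
                       model_params(D = 1, gamma = 1), k, g, cfg)$u_final,
         g = g)
  }
  a <- sol_dx(0.02); b <- sol_dx(0.01); c <- sol_dx(0.005)
  on_a <- function(s) s$u[match(round(a$g$x, 10), round(s$g$x, 10))]
  r_dx <- max(abs(a$u - on_a(b))) / max(abs(on_a(b) - on_a(c)))
  expect_gt(r_dx, 2.5)
  expect_lt(r_dx, 8)
})

test_that("trajectories round-trip through CSV + JSON metadata", {
  g <- build_grid(1, 0.02)
  k <- top_hat_kernel(0.1, g)
  u0 <- single_peak(0.1, 1, 1, std_sigma, g)
  cfg <- numerics_config(t_end = 0.01, dt = 1e-5, record_every = 0.002,
                         steady_check_lag = 0, seed = 99)
  tr <- quiet_run(u0, model_params(), k, g, cfg)
  csv <- tempfile(fileext = ".csv")
  js <- tempfile(fileext = ".json")
  write_trajectory_csv(tr, csv, js)
  back <- read_trajectory_csv(csv, js)
  expect_equal(back$times, tr$times)
  expect_equal(back$snapshots, tr$snapshots, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$params$gamma, 10)
  expect_equal(back$kernel_meta$sigma2, k$sigma2)
  expect_equal(back$stop_reason, tr$stop_reason)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(meta$numerics$seed, 99)
})

test_that("snapshot_at retrieves the nearest recorded state", {
  g <- std_grid()
  k <- std_kernel(g)
  cfg <- numerics_config(t_end = 0.01, dt = 1e-5, record_every = 0.002,
                         steady_check_lag = 0)
  tr <- quiet_run(single_peak(0.1, 1, 1, std_sigma, g), model_params(),
                  k, g, cfg)
  expect_identical(snapshot_at(tr, 0), tr$snapshots[, 1])
  expect_identical(snapshot_at(tr, 1e9), tr$u_final)
})
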
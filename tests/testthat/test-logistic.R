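test_that("logistic reaction: fixed points, vertex, saturation of the ODE", {
  p <- ref_params()
  expect_equal(logistic_reaction(0, p), 0)
  expect_equal(logistic_reaction(1, p), 0)
  n <- seq(0, 1, by = 0.01)
  expect_equal(n[which.max(logistic_reaction(n, p))], 0.5)
  # saturation of the non-spatial model at carrying capacity
  expect_equal(logistic_ode_limit(0.5, p, t_end = 5000), 1,
               tolerance = 1e-6)
  # generalized carrying capacity rescales the limit
  p3 <- model_params(D = 1, r = 0.01, N_inf = 3)
  expect_equal(logistic_ode_limit(0.5, p3, t_end = 5000), 3,
               tolerance = 1e-5)
})

test_that("auxiliary front constants", {
  # frozen high-precision evaluation of the quoted constant at N0 = 0.5
  expect_equal(logistic_k0(0.5), 0.04554884989667767, tolerance = 1e-12)
  expect_equal(logistic_k0(1), 0)
  expect_equal(logistic_kappa(1), 0)
  n0 <- seq(0, 1, by = 0.05)
  expect_true(all(diff(logistic_k0(n0)) < 0))      # strictly decreasing
  expect_true(all(logistic_k0(n0) >= 0 & logistic_k0(n0) < 1))
  # sign follows 1 - N0 for both constant sets
  expect_lt(logistic_k0(1.5), 0)
  expect_lt(logistic_kappa(1.5), 0)
  expect_error(logistic_k0(7), "\\[0, 7\\)")
})

test_that("stationary front: boundary value, inland limit, degenerate case", {
  for (form in c("exact", "printed")) {
    for (n0 in c(0.2, 0.5, 0.9, 1.3)) {
      fr <- stationary_logistic_profile(model_params(D = 1, r = 0.01,
                                                     N0 = n0), form = form)
      expect_equal(stationary_profile(0, fr), n0)
      expect_equal(stationary_profile(200, fr), 1, tolerance = 1e-8)
      # the two algebraic spellings agree pointwise
      x <- seq(0, 80, by = 4)
      expect_equal(stationary_profile(x, fr),
                   stationary_profile(x, fr, representation = "growing"))
    }
    fr1 <- stationary_logistic_profile(model_params(D = 1, r = 0.01,
                                                    N0 = 1), form = form)
    expect_equal(stationary_profile(c(0, 5, 50), fr1), rep(1, 3))
  }
  # monotone approach from below for 0 < N0 < 1
  fr <- stationary_logistic_profile(model_params(D = 1, r = 0.01, N0 = 0.5))
  x <- seq(0, 100, by = 0.5)
  v <- stationary_profile(x, fr)
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 0.5 & v < 1))
})

test_that("near-carrying-capacity approximation tightens as N0 -> 1", {
  x <- seq(0, 100, by = 0.1)           # [0, 10 x_G]
  gap_to <- function(n0, form) {
    p <- model_params(D = 1, r = 0.01, N0 = n0)
    fr <- stationary_logistic_profile(p, form = form)
    max(abs(stationary_profile_approx(x, p) - stationary_profile(x, fr)))
  }
  for (form in c("exact", "printed")) {
    gaps <- vapply(c(0.5, 0.9, 0.99), gap_to, numeric(1), form = form)
    expect_true(all(diff(gaps) < 0))
    expect_lt(gaps[3], 1e-3)
  }
  p9 <- model_params(D = 1, r = 0.01, N0 = 0.9)
  expect_equal(stationary_profile_approx(0, p9), 0.9)
  expect_equal(stationary_profile_approx(1e4, p9), 1)
  p1 <- model_params(D = 1, r = 0.01, N0 = 1)
  expect_equal(stationary_profile_approx(c(0, 7, 60), p1), rep(1, 3))
})

test_that("transitional zone has width x_G", {
  # the linearised front satisfies |N - 1| < 0.05 |N0 - 1| beyond 3 x_G
  # exactly (e^-3 < 0.05); the closed forms carry a slightly larger decay
  # prefactor, so they are checked from 3.5 x_G on
  xg <- 10
  for (n0 in c(0.5, 0.9, 1.2)) {
    p <- model_params(D = 1, r = 0.01, N0 = n0)
    x3 <- seq(3 * xg + 1e-9, 20 * xg, by = 1)
    expect_true(all(abs(stationary_profile_approx(x3, p) - 1) <
                      0.05 * abs(n0 - 1)))
    x35 <- seq(3.5 * xg, 20 * xg, by = 1)
    for (form in c("exact", "printed")) {
      fr <- stationary_logistic_profile(p, form = form)
      expect_true(all(abs(stationary_profile(x35, fr) - 1) <
                        0.05 * abs(n0 - 1)))
    }
  }
})

test_that("stationarity residual oracle: exact solves, printed does not", {
  p <- model_params(D = 1, r = 0.01, N0 = 0.5)
  xg <- 10
  fr_exact <- stationary_logistic_profile(p)
  expect_lt(stationary_residual(fr_exact, spacing = 1e-3 * xg),
            1e-6 * p$r)
  # uniform carrying-capacity state is exactly stationary
  expect_equal(stationary_residual(function(x) rep(1, length(x)),
                                   spacing = 0.05, params = p), 0)
  # an additive perturbation is detected
  pert <- function(x) stationary_profile(x, fr_exact) + 0.01
  expect_gt(stationary_residual(pert, spacing = 1e-3 * xg, params = p),
            1e-4 * p$r)
  # the printed-form constants solve D N'' + (r/2)(1 - N^2) = 0 instead:
  # their logistic residual equals -r (1 - N)^2 / 2 pointwise
  fr_printed <- stationary_logistic_profile(p, form = "printed")
  x <- seq(0.1, 100, by = 0.1)
  n <- stationary_profile(x, fr_printed)
  h <- 1e-3 * xg
  lap <- (stationary_profile(x + h, fr_printed) - 2 * n +
            stationary_profile(pmax(x - h, 0), fr_printed)) / h^2
  resid <- p$D * lap + logistic_reaction(n, p)
  expect_equal(resid, -p$r * (1 - n)^2 / 2, tolerance = 1e-6)
  expect_gt(stationary_residual(fr_printed, spacing = 1e-3 * xg),
            1e-2 * p$r)
  expect_error(stationary_residual(fr_exact, spacing = 1), "spacing")
})

test_that("the time-dependent solution drifts toward the exact front", {
  # short-horizon monitoring on a coarser grid; the full default-resolution
  # convergence contract is exercised by the acceptance suite
  p <- model_params(D = 1, r = 0.01, N0 = 0.5)
  g <- spatial_grid(100, spacing = 0.2)
  req <- solve_request(p, g, "logistic",
                       left = boundary_spec("coast", "dirichlet-constant",
                                            value = 0.5),
                       snapshot_times = c(100, 400, 800, 1200), dt = 0.25,
                       monitor_far_field = FALSE)
  fr <- stationary_logistic_profile(p)
  gaps <- steady_state_gap(rd_solve(req),
                           function(x) stationary_profile(x, fr))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[4], 1e-2)
})
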
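test_that("request validation", {
  p <- ref_params()
  g <- spatial_grid(10, spacing = 0.1)
  expect_error(solve_request(p, g, "none", snapshot_times = c(2, 1)),
               "strictly increasing")
  expect_error(solve_request(p, g, "none", snapshot_times = 1, dt = 2),
               "dt")
  expect_error(solve_request(model_params(D = 1, r = 0), g, "exponential",
                             snapshot_times = 1), "r > 0")
  expect_error(solve_request(p, g, "none", snapshot_times = 1,
                             initial = rep(1, 5)), "per grid node")
  expect_error(boundary_spec("coast", "dirichlet-exponential", rate = -1),
               "rate")
  expect_error(solve_request(p, spatial_grid(1, n_nodes = 2), "none",
                             snapshot_times = 1), "3 grid nodes")
})

test_that("pure diffusion matches the erfc solution on a short domain", {
  p <- model_params(D = 1, N0 = 1)
  g <- spatial_grid(20, spacing = 0.05)   # default (contract) resolution
  sol <- rd_solve(solve_request(p, g, "none", snapshot_times = c(0.1, 1)))
  gaps <- steady_state_gap(sol, function(x) model1_density(x, 1, p))
  expect_lt(gaps[2], 1e-3)
  expect_lt(max(abs(sol[[1]]$values - model1_density(grid_nodes(g), 0.1, p))),
            1e-3)
  # earliest snapshot already shows the boundary layer: monotone decrease
  expect_true(all(diff(sol[[1]]$values) <= 0))
  # comparison principle: nonnegative data keep the solution nonnegative
  for (f in sol) expect_true(all(f$values >= 0))
})

test_that("halving the spacing cuts the error about fourfold", {
  p <- model_params(D = 1, N0 = 1)
  err <- function(h) {
    g <- spatial_grid(20, spacing = h)
    sol <- rd_solve(solve_request(p, g, "none", snapshot_times = 0.5,
                                  dt = 0.002))
    max(abs(sol[[1]]$values - model1_density(grid_nodes(g), 0.5, p)))
  }
  ratio <- err(0.2) / err(0.1)
  expect_gte(ratio, 3)
  expect_lte(ratio, 5)
})

test_that("zero-flux pure diffusion conserves total population", {
  p <- model_params(D = 1, N0 = 1)
  g <- spatial_grid(40, spacing = 0.1)
  x <- grid_nodes(g)
  bump <- exp(-(x - 20)^2 / 4)
  req <- solve_request(p, g, "none",
                       left = boundary_spec("coast", "neumann-zero"),
                       right = boundary_spec("inland", "neumann-zero"),
                       snapshot_times = c(10, 50, 100), dt = 0.1,
                       initial = bump, monitor_far_field = FALSE)
  sol <- rd_solve(req)
  m0 <- integrate_field(density_field(g, bump))
  for (f in sol)
    expect_equal(integrate_field(f), m0, tolerance = 1e-8)
})

test_that("exponential growth with synchronised boundary tracks closed form", {
  p <- ref_params()
  g <- spatial_grid(30, spacing = 0.1)
  req <- solve_request(p, g, "exponential",
                       left = boundary_spec("coast", "dirichlet-exponential",
                                            value = 1, rate = 0.01),
                       snapshot_times = c(1, 10))
  gaps <- steady_state_gap(rd_solve(req),
                           function(x) model2_sync_density(x, 10, p))
  expect_lt(gaps[2], 1e-3)
})

test_that("band steady wave is held stationary by the integrator", {
  p <- ref_params()
  cfg <- band_config(L = 15, A = 0.2, B = 1, x_G = 10)
  g <- spatial_grid(15, spacing = 0.05)
  init <- band_steady_density(grid_nodes(g), cfg)
  req <- solve_request(p, g, "exponential",
                       left = boundary_spec("coast", "dirichlet-constant",
                                            value = 0.2),
                       right = boundary_spec("inland", "dirichlet-constant",
                                             value = 1),
                       snapshot_times = c(25, 100), initial = init,
                       monitor_far_field = FALSE)
  drift <- steady_state_gap(rd_solve(req),
                            function(x) band_steady_density(x, cfg))
  expect_lt(max(drift), 1e-4)
})

test_that("steady_state_gap contracts", {
  p <- model_params(D = 1, N0 = 1)
  g <- spatial_grid(10, spacing = 0.1)
  f <- density_field(g, model1_density(grid_nodes(g), 5, p), time = 5)
  expect_equal(steady_state_gap(list(f), f), 0)
  g2 <- spatial_grid(10, spacing = 0.2)
  f2 <- density_field(g2, model1_density(grid_nodes(g2), 5, p))
  expect_error(steady_state_gap(list(f, f2), f), "incompatible")
  expect_error(steady_state_gap(list(f), f2), "incompatible")
})

test_that("far-field validity monitor warns when truncation is too tight", {
  p <- model_params(D = 1, N0 = 1)
  g <- spatial_grid(5, spacing = 0.1)    # much too short for t = 10
  req <- solve_request(p, g, "none", snapshot_times = 10, dt = 0.1)
  expect_warning(rd_solve(req), "truncation")
  sol <- suppressWarnings(rd_solve(req))
  expect_true(attr(sol, "far_field_warning"))
})
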
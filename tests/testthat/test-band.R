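test_that("band profile: edge values, symmetry, stationarity residual", {
  cfg <- band_config(L = 15, A = 0.3, B = 1.2, x_G = 10)
  expect_equal(band_steady_density(0, cfg), 0.3)
  expect_equal(band_steady_density(15, cfg), 1.2)

  sym <- band_config(L = 20, A = 0.7, B = 0.7, x_G = 10)
  xs <- seq(0, 10, by = 0.5)
  expect_equal(band_steady_density(xs, sym),
               band_steady_density(20 - xs, sym))

  # finite-difference oracle on r N + D N'' = 0 (D = 1, r = 0.01)
  h <- 1e-3 * 10
  x <- seq(h, 15 - h, by = 0.1)
  lap <- (band_steady_density(x + h, cfg) - 2 * band_steady_density(x, cfg) +
            band_steady_density(x - h, cfg)) / h^2
  resid <- 0.01 * band_steady_density(x, cfg) + 1 * lap
  expect_lt(max(abs(resid)), 1e-6)

  expect_error(band_config(L = 40, A = 0, B = 1, x_G = 10), "existence")
  expect_error(band_steady_density(16, cfg), "\\[0, L\\]")
})

test_that("band total: half-angle value, quadrature oracle, limits", {
  xg <- 10
  cfg <- band_config(L = pi / 2 * xg, A = 0.4, B = 0.4, x_G = xg)
  expect_equal(band_total(cfg), 2 * 0.4 * xg)     # tan(pi/4) = 1

  cfg2 <- band_config(L = 22, A = 0.1, B = 0.9, x_G = xg)
  quad <- stats::integrate(function(x) band_steady_density(x, cfg2),
                           0, 22, rel.tol = 1e-10)$value
  expect_equal(band_total(cfg2), quad, tolerance = 1e-6)

  tiny <- band_config(L = 1e-6, A = 1, B = 1, x_G = xg)
  expect_lt(band_total(tiny), 1e-5)
  expect_error(band_total(band_config(L = pi * xg, A = 0, B = 1, x_G = xg)),
               "diverges")
})

test_that("band occupancy pdf: normalisation, shape, consistency", {
  for (cfg in list(band_config(10, 0, 1, 10),
                   band_config(25, 0.5, 1.5, 10),
                   band_config(pi, 1, 1, 1),
                   band_config(2.8, 2, 0.1, 1))) {
    norm <- stats::integrate(function(x) band_occupancy_pdf(x, cfg),
                             0, cfg$L, rel.tol = 1e-10)$value
    expect_equal(norm, 1, tolerance = 1e-8)
  }
  # empty coastal edge: density vanishes at the coast and rises inland
  cfg <- band_config(12, 0, 1, 10)
  expect_equal(band_occupancy_pdf(0, cfg), 0)
  x <- seq(0, 12, by = 0.5)
  expect_true(all(diff(band_occupancy_pdf(x, cfg)) > 0))
  # ratio consistency with the profile
  cfg2 <- band_config(18, 0.2, 1, 10)
  expect_equal(band_occupancy_pdf(x, cfg2),
               band_steady_density(x, cfg2) / band_total(cfg2),
               tolerance = 1e-12)
  # pdf stays finite at the window edge L = pi * x_G
  edge <- band_config(pi * 10, 0, 1, 10)
  expect_true(all(is.finite(band_occupancy_pdf(c(0, 15, 31.4), edge))))
})

test_that("band entropy: uniform limit, A-B symmetry, reproducibility", {
  xg <- 10
  # narrow equal-edge band tends to the uniform law: H -> ln L
  L <- 1e-3 * xg
  expect_equal(band_entropy(band_config(L, 1, 1, xg)), log(L),
               tolerance = 1e-4)
  for (ab in list(c(0, 1), c(0.3, 1.1), c(2, 0.5)))
    expect_equal(band_entropy(band_config(17, ab[1], ab[2], xg)),
                 band_entropy(band_config(17, ab[2], ab[1], xg)),
                 tolerance = 1e-9)
  h1 <- band_entropy(band_config(20, 0, 1, xg), rel_tol = 1e-6)
  h2 <- band_entropy(band_config(20, 0, 1, xg), rel_tol = 1e-10)
  expect_equal(h1, h2, tolerance = 1e-6)
  expect_true(is.finite(h1))
})

test_that("plane-angle arctangent: axes, quadrants, sign formula", {
  expect_equal(arctan_xy(1, 0), 0)
  expect_equal(arctan_xy(0, 1), pi / 2)
  expect_equal(arctan_xy(-1, 0), pi)
  expect_error(arctan_xy(0, 0), "undefined")
  # agrees with atan2 on the upper unit semicircle
  for (th in seq(0.05, pi - 0.05, length.out = 20))
    expect_equal(arctan_xy(cos(th), sin(th)), atan2(sin(th), cos(th)))
})

test_that("closed-form optimal width: special values, limits, monotonicity", {
  xg <- 10
  expect_equal(optimal_band_width_closed(xg, C = 1), pi / 2 * xg)
  expect_lt(optimal_band_width_closed(xg, C = 1e-9), 1e-7)
  expect_equal(optimal_band_width_closed(xg, C = 1e9), pi * xg,
               tolerance = 1e-8)
  Cs <- 10^seq(-2, 2, length.out = 100)
  ls <- vapply(Cs, function(C) optimal_band_width_closed(xg, C), numeric(1))
  expect_true(all(diff(ls) > 0))                     # strict monotonicity
  expect_true(all(ls > 0 & ls <= pi * xg))
  expect_equal(ls, 2 * xg * atan(Cs))                # half-angle identity
  expect_error(optimal_band_width_closed(xg, C = 0), "`C`")
})

test_that("numerical entropy maximiser: window, symmetry, scale freedom", {
  xg <- 3
  l1 <- optimal_band_width_numeric(0.4, 1.3, xg)
  expect_true(l1 > 0 && l1 <= pi * xg)
  l2 <- optimal_band_width_numeric(1.3, 0.4, xg)
  expect_equal(l1, l2, tolerance = 1e-5 * xg)        # A <-> B reflection
  l3 <- optimal_band_width_numeric(0.4 * 7, 1.3 * 7, xg)
  expect_equal(l1, l3, tolerance = 1e-5 * xg)        # joint scaling
})

test_that("band width report: C convention, both widths, skewed mode", {
  rep1 <- band_width_report(A = 0, B = 1, x_G = 1)
  expect_equal(rep1$config$C, 1)                     # C = x_G when A = 0
  expect_equal(rep1$L_star_closed, pi / 2)
  for (xg in c(0.5, 2, 10))
    expect_equal(band_width_report(0, 1, xg)$config$C, xg)
  rep2 <- band_width_report(A = 0, B = 1, x_G = 10)
  expect_true(is.finite(rep2$L_star_closed) && is.finite(rep2$L_star_numeric))
  expect_gte(rep2$discrepancy, 0)
  expect_equal(rep2$discrepancy,
               abs(rep2$L_star_closed - rep2$L_star_numeric))

  # coastward-skewed occupancy at the closed-form width when A = 0:
  # the mode sits strictly inside (L*/2, L*]
  for (xg in c(2, 10)) {
    r <- band_width_report(0, 1, xg)
    xs <- seq(0, r$L_star_closed, length.out = 2001)
    mode_x <- xs[which.max(band_occupancy_pdf(xs, r$config))]
    expect_gt(mode_x, r$L_star_closed / 2)
    expect_lte(mode_x, r$L_star_closed)
  }
})
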
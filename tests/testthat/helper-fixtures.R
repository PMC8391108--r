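# Shared fixtures: the reference parameterisation (D = 1 km^2/yr,
# r = 0.01/yr, so x_G = 10 km) and small helper builders.

ref_params <- function(N0 = 1) model_params(D = 1, r = 0.01, N0 = N0)

# a model-1 analytic field on [0, x_max]
model1_field <- function(t, x_max = 100, spacing = 0.1, params = ref_params()) {
  g <- spatial_grid(x_max, spacing = spacing)
  density_field(g, model1_density(grid_nodes(g), t, params), time = t)
}

# internal scenario -> solve_request translator (not part of the API)
solver_request_of_test <- function(config) coastdiff:::solver_request_of(config)

# high-precision erfc oracle independent of pnorm: direct quadrature of
# the defining integral (2/sqrt(pi)) int_y^Inf exp(-z^2) dz
erfc_quad <- function(y)
  2 / sqrt(pi) * stats::integrate(function(z) exp(-z^2), lower = y,
                                  upper = Inf, rel.tol = 1e-13)$value
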
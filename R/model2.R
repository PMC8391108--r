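# Exponential growth-diffusion on the half-line.  The substitution
# N = exp(r t) * Ntilde maps the model onto pure diffusion, so the
# synchronised-boundary solution is the erfc profile times exp(r t), while
# the constant-boundary ("regulated central business district") solution
# comes from Duhamel's principle and is evaluated by adaptive quadrature.

#' Exponential growth-diffusion density, synchronised coastal boundary
#'
#' Solution of `dN/dt = r N + D d2N/dx2` when the coastal density grows in
#' step with the interior, `N(0, t) = N0 exp(r t)`:
#' `N(x, t) = N0 exp(r t) erfc(x / (2 sqrt(D t)))`.
#'
#' @inheritParams model1_density
#' @param params A [model_params()] with `r > 0`.
#' @return Dimensionless density, same length as `x`.
#' @export
model2_sync_density <- function(x, t, params) {
  params <- as_coast_params(params)
  if (params$r <= 0) stop("`r` must be > 0 for the growth-diffusion model")
  exp(params$r * t) * model1_density(x, t, params)
}

#' Total population, synchronised boundary
#'
#' `N*(t) = 2 N0 sqrt(D t / pi) exp(r t)`: the pure-diffusion total times
#' the growth factor.
#'
#' @inheritParams model2_sync_density
#' @return Total population (density times km), vectorised over `t`.
#' @export
model2_sync_total <- function(t, params) {
  params <- as_coast_params(params)
  if (params$r <= 0) stop("`r` must be > 0 for the growth-diffusion model")
  exp(params$r * t) * model1_total(t, params)
}

#' Duhamel kernel integral of the regulated-boundary solution
#'
#' Evaluates `F(a, b) = integral_0^a w^(-3/2) exp(w - b^2/(4w)) dw`, the
#' kernel integral arising when the constant coastal boundary condition is
#' propagated by Duhamel's principle.  The `exp(-b^2/(4w))` factor shields
#' the `w^(-3/2)` singularity, so the integral is finite for every finite
#' `a` (and divergent as `a` grows without bound, which is the analytic
#' signature of unbounded growth outside the regulated coast).
#'
#' Numerically the substitution `v = b^2/(4w)` is applied to the whole
#' range, turning the near-singular factor into a well-behaved
#' `v^(-1/2) exp(-v)` tail whatever the size of `b`; the integrand is
#' scaled by the maximum of its exponent before quadrature to avoid
#' overflow.
#'
#' @param a Dimensionless upper limit, `a = r t >= 0`.
#' @param b Dimensionless position, `b = x / x_G > 0` (at `b = 0` the
#'   singularity is unshielded and the integral diverges).
#' @param rel_tol Relative quadrature tolerance, in `(0, 1e-4]`.
#' @return The (dimensionless) value of the integral.
#' @export
duhamel_F <- function(a, b, rel_tol = 1e-10) {
  stopifnot(length(a) == 1L, length(b) == 1L, is.finite(a), is.finite(b))
  if (a < 0) stop("`a` must be >= 0")
  if (b < 0) stop("`b` must be >= 0")
  if (!(rel_tol > 0 && rel_tol <= 1e-4))
    stop("`rel_tol` must be in (0, 1e-4]")
  if (a == 0) return(0)
  if (b == 0)
    stop("divergent integral: the w^(-3/2) singularity is unshielded at b = 0")
  # v = b^2/(4w) maps (0, a] onto [b^2/(4a), Inf) and turns the integrand
  # into (2/b) v^(-1/2) exp(b^2/(4v) - v): the exponent is strictly
  # decreasing with maximum a - b^2/(4a) at the lower limit, so after
  # scaling by that maximum the integrand is bounded by v^(-1/2) e^(-v)
  # for every a and b -- no residual singularity, no overflow
  v0 <- b^2 / (4 * a)
  m <- a - v0                                 # exponent max, at v = v0
  2 / b * exp(m) * stats::integrate(
    function(v) v^(-0.5) * exp(b^2 / (4 * v) - v - m),
    lower = v0, upper = Inf, rel.tol = rel_tol)$value
}

#' Exponential growth-diffusion density, regulated coastal boundary
#'
#' Solution of `dN/dt = r N + D d2N/dx2` when the coastal density is held
#' constant, `N(0, t) = N0` (density regulation in the central business
#' district):
#' `N(x, t) = (N0 / (2 sqrt(pi))) * (x / x_G) * F(r t, x / x_G)`,
#' with `F` the Duhamel kernel integral [duhamel_F()] and
#' `x_G = sqrt(D / r)`.  The coastal value `N0` is recovered continuously as
#' `x` tends to 0; at any fixed `x > 0` the density grows without bound as
#' `t` grows, so the regulation does not cap growth outside the coast.
#'
#' @inheritParams model2_sync_density
#' @param rel_tol Relative quadrature tolerance passed to [duhamel_F()].
#' @return Dimensionless density, same length as `x`.
#' @examples
#' p <- model_params(D = 1, r = 0.01)
#' model2_cbd_density(5, 50, p)  # ~ 0.7301
#' @export
model2_cbd_density <- function(x, t, params, rel_tol = 1e-10) {
  params <- as_coast_params(params)
  if (params$r <= 0) stop("`r` must be > 0 for the growth-diffusion model")
  stopifnot(length(t) == 1L)
  check_xt(x, t)
  if (t == 0) return(numeric(length(x)))
  xg <- characteristic_length(params)
  a <- params$r * t
  vapply(x, function(xi) {
    if (xi == 0) return(params$N0)              # maintained boundary value
    b <- xi / xg
    params$N0 / (2 * sqrt(pi)) * b * duhamel_F(a, b, rel_tol)
  }, numeric(1))
}

#' Imaginary error function
#'
#' `erfi(z) = (2 / sqrt(pi)) * integral_0^z exp(s^2) ds`, computed from its
#' Maclaurin series `erfi(z) = (2/sqrt(pi)) sum z^(2n+1) / (n! (2n+1))`.
#' All series terms are positive, so there is no cancellation; the series is
#' truncated at machine precision.  Overflows (returns `Inf`) for
#' `z` beyond about 26.6, as does the function itself in double precision.
#'
#' @param z Real argument (vectorised).
#' @return `erfi(z)`.
#' @export
erfi <- function(z) {
  vapply(z, function(zi) {
    if (!is.finite(zi) || zi == 0) return(zi)
    s <- sign(zi); zi <- abs(zi)
    term <- zi; total <- zi; n <- 0
    z2 <- zi^2
    while (TRUE) {
      n <- n + 1
      term <- term * z2 / n
      contrib <- term / (2 * n + 1)
      total <- total + contrib
      if (!is.finite(total) || contrib <= total * 1e-17) break
    }
    s * 2 / sqrt(pi) * total
  }, numeric(1))
}

#' Total population, regulated coastal boundary
#'
#' `N*(t) = (N0 x_G / sqrt(pi)) * integral_0^{rt} w^(-1/2) exp(w) dw`,
#' equal in closed form to `N0 x_G erfi(sqrt(r t))`.  Both evaluation routes
#' are available and agree to the quadrature tolerance; for small `r t` the
#' total reduces to the pure-diffusion law `2 N0 sqrt(D t / pi)`.
#'
#' @inheritParams model2_sync_total
#' @param method `"erfi"` (default, series closed form) or `"quadrature"`
#'   (adaptive quadrature of the defining integral).
#' @return Total population (density times km), vectorised over `t`.
#' @export
model2_cbd_total <- function(t, params, method = c("erfi", "quadrature")) {
  params <- as_coast_params(params)
  method <- match.arg(method)
  if (params$r <= 0) stop("`r` must be > 0 for the growth-diffusion model")
  if (any(t < 0)) stop("`t` must be >= 0")
  xg <- characteristic_length(params)
  vapply(t, function(ti) {
    a <- params$r * ti
    if (a == 0) return(0)
    if (method == "erfi") return(params$N0 * xg * erfi(sqrt(a)))
    q <- stats::integrate(function(w) w^(-0.5) * exp(w), lower = 0,
                          upper = a, rel.tol = 1e-10)$value
    params$N0 * xg / sqrt(pi) * q
  }, numeric(1))
}
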
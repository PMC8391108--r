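# Pure diffusion from a step coastal boundary: the density profile is the
# complementary error function, so every aggregate has a closed form.

# erfc via the normal CDF: erfc(y) = 2 * pnorm(-y * sqrt(2)); accurate on
# the far tail (pnorm works on the log scale internally).
erfc <- function(y) 2 * pnorm(y * sqrt(2), lower.tail = FALSE)

check_xt <- function(x, t) {
  if (any(x < 0)) stop("`x` must be >= 0 (distance from the coast)")
  if (any(t < 0)) stop("`t` must be >= 0")
}

#' Pure-diffusion density profile
#'
#' Closed-form solution of `dN/dt = D d2N/dx2` on the half-line with zero
#' initial density, a step coastal boundary `N(0, t) = N0` for `t > 0`, and
#' decay at infinity:
#' `N(x, t) = N0 * erfc(x / (2 sqrt(D t)))`.
#' At `t = 0` the zero initial field is returned everywhere, including the
#' coast; for `t > 0` the coastal node takes the maintained value `N0`.
#'
#' @param x Distance from the coast, km (vectorised, non-negative).
#' @param t Time in yr (scalar, non-negative).
#' @param params A [model_params()] object (`r` is ignored).
#' @return Dimensionless density, same length as `x`.
#' @examples
#' p <- model_params(D = 1, N0 = 1)
#' model1_density(10, 100, p)  # erfc(0.5) ~ 0.4795
#' @export
model1_density <- function(x, t, params) {
  params <- as_coast_params(params)
  stopifnot(length(t) == 1L)
  check_xt(x, t)
  if (t == 0) return(numeric(length(x)))
  params$N0 * erfc(x / (2 * sqrt(params$D * t)))
}

#' Total population under pure diffusion
#'
#' `N*(t) = 2 N0 sqrt(D t / pi)`: the integral of the erfc profile over the
#' half-line.  Grows like the square root of time.
#'
#' @inheritParams model1_density
#' @return Total population (density times km), vectorised over `t`.
#' @export
model1_total <- function(t, params) {
  params <- as_coast_params(params)
  if (any(t < 0)) stop("`t` must be >= 0")
  2 * params$N0 * sqrt(params$D * t / pi)
}

#' Occupancy distribution under pure diffusion
#'
#' Probability density of an inhabitant's living location,
#' `p(x, t) = N(x, t) / N*(t)`.  Two algebraically identical forms are
#' provided: the density/total ratio, and the explicit integral form
#' `p(x, t) = (1 / sqrt(D t)) * integral exp(-y^2) dy` from
#' `x / (2 sqrt(D t))` to infinity, evaluated by adaptive quadrature.
#'
#' @inheritParams model1_density
#' @param t Time in yr; must be positive (the distribution is undefined at
#'   `t = 0`).
#' @param form `"ratio"` (default, closed form) or `"integral"` (explicit
#'   quadrature form, mainly for cross-checks).
#' @return Probability density in 1/km, same length as `x`.
#' @export
model1_occupancy_pdf <- function(x, t, params,
                                 form = c("ratio", "integral")) {
  params <- as_coast_params(params)
  form <- match.arg(form)
  stopifnot(length(t) == 1L)
  if (t <= 0) stop("occupancy distribution undefined for t <= 0")
  check_xt(x, t)
  if (form == "ratio")
    return(model1_density(x, t, params) / model1_total(t, params))
  s <- sqrt(params$D * t)
  vapply(x, function(xi) {
    stats::integrate(function(y) exp(-y^2), lower = xi / (2 * s),
                     upper = Inf, rel.tol = 1e-12)$value / s
  }, numeric(1))
}

#' Moments of the pure-diffusion occupancy distribution
#'
#' Closed forms: mean `sqrt(pi D t) / 2 * ...` i.e.
#' `mean = (sqrt(pi)/2) sqrt(D t)`, second moment `(4/3) D t`, variance
#' `(4/3 - pi/4) D t ~ 0.55 D t`.  The variance coefficient is the average
#' inland spread rate (km^2/yr per unit `D`).
#'
#' @inheritParams model1_occupancy_pdf
#' @return A `"coast_moments"` object (see [field_moments()]).
#' @export
model1_moments <- function(t, params) {
  params <- as_coast_params(params)
  stopifnot(length(t) == 1L)
  if (t <= 0) stop("moments undefined for t <= 0")
  Dt <- params$D * t
  mean_x <- sqrt(pi) / 2 * sqrt(Dt)
  second <- 4 / 3 * Dt
  structure(list(total = model1_total(t, params), mean_x = mean_x,
                 second_moment = second, variance = second - mean_x^2),
            class = "coast_moments")
}
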
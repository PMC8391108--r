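# Logistic growth-diffusion: stationary coastal front and its
# near-carrying-capacity approximation.  Two sets of constants are carried
# for the stationary profile: the "exact" pair, which makes the profile an
# exact solution of D N'' + r N (1 - N) = 0 (verified symbolically and by
# the finite-difference residual oracle), and the "printed" pair from the
# widely quoted variant of these constants, which actually solves
# D N'' + (r/2)(1 - N^2) = 0 and therefore misses the logistic equation by
# a residual of exactly -r (1 - N)^2 / 2.  Both hit N(0) = N0 and approach
# the carrying capacity inland; they differ by O(10^-2) at N0 = 0.5.  See
# the vignette for the full story.

#' Logistic reaction term
#'
#' `f(N) = r N (1 - N / N_inf)`: zero at the empty state and at carrying
#' capacity, maximal at `N_inf / 2`.
#'
#' @param N Density (non-negative, vectorised).
#' @param params A [model_params()].
#' @return Growth rate in 1/yr, same length as `N`.
#' @export
logistic_reaction <- function(N, params) {
  params <- as_coast_params(params)
  if (any(N < 0)) stop("`N` must be >= 0")
  params$r * N * (1 - N / params$N_inf)
}

#' Auxiliary constants of the stationary logistic front
#'
#' `logistic_k0()` is the commonly quoted auxiliary constant
#' `K0 = (sqrt(3) - sqrt(2 + N0)) / (sqrt(3) + sqrt(2 + N0))`;
#' `logistic_kappa()` is the corrected constant
#' `kappa = (sqrt(3) - sqrt(1 + 2 N0)) / (sqrt(3) + sqrt(1 + 2 N0))`
#' under which the Moebius-form front solves the logistic stationary
#' equation exactly.  Both vanish iff `N0 = 1` and share the sign of
#' `1 - N0`.
#'
#' @param N0 Coastal boundary density; must lie in `[0, 7)` for `K0`
#'   (where `K0 > -1`) and the same range is enforced for `kappa`.
#' @return The dimensionless constant.
#' @examples
#' logistic_k0(0.5)     # ~ 0.045549
#' logistic_kappa(0.5)  # ~ 0.101021
#' @export
logistic_k0 <- function(N0) {
  check_logistic_N0(N0)
  (sqrt(3) - sqrt(2 + N0)) / (sqrt(3) + sqrt(2 + N0))
}

#' @rdname logistic_k0
#' @export
logistic_kappa <- function(N0) {
  check_logistic_N0(N0)
  (sqrt(3) - sqrt(1 + 2 * N0)) / (sqrt(3) + sqrt(1 + 2 * N0))
}

check_logistic_N0 <- function(N0) {
  if (any(N0 < 0) || any(N0 >= 7))
    stop("`N0` must lie in [0, 7) for the stationary logistic front")
  invisible(N0)
}

#' Stationary front of the logistic growth-diffusion model
#'
#' Constructs the time-independent profile to which the logistic model with
#' a constant coastal boundary `N(0) = N0` converges, a Moebius/tanh^2
#' front approaching the carrying capacity inland over the length scale
#' `x_G = sqrt(D / r)`.  With `form = "exact"` (default) the constants make
#' the profile an exact stationary solution,
#' `N(x) = (3/2) ((1 - kappa e)/(1 + kappa e))^2 - 1/2`,
#' `e = exp(-x / x_G)`; with `form = "printed"` the commonly quoted constants are
#' used, `N(x) = 3 ((1 - K0 e)/(1 + K0 e))^2 - 2`, whose stationary
#' residual is `-r (1 - N)^2 / 2` (see [stationary_residual()]).
#'
#' A carrying-capacity scale `N_inf != 1` is handled by normalising on
#' entry and rescaling on exit.  `N0 >= 7` (where the constants would leave
#' their admissible range) is rejected.
#'
#' @param params A [model_params()] with `r > 0`; `params$N0` is the
#'   coastal value, in units of `N_inf`... more precisely the boundary
#'   density divided by `N_inf` must lie in `[0, 7)`.
#' @param form `"exact"` or `"printed"` constants (see Details).
#' @return An object of class `"coast_logistic_front"`: list with `params`,
#'   `form`, `x_G`, `K` (the Moebius constant used) and `N0` (normalised
#'   coastal value).
#' @examples
#' fr <- stationary_logistic_profile(model_params(D = 1, r = 0.01, N0 = 0.5))
#' stationary_profile(c(0, 10, 50), fr)
#' @export
stationary_logistic_profile <- function(params, form = c("exact", "printed")) {
  params <- as_coast_params(params)
  form <- match.arg(form)
  if (params$r <= 0) stop("`r` must be > 0 for the logistic front")
  n0 <- params$N0 / params$N_inf
  K <- if (form == "exact") logistic_kappa(n0) else logistic_k0(n0)
  structure(list(params = params, form = form,
                 x_G = characteristic_length(params), K = K, N0 = n0),
            class = "coast_logistic_front")
}

#' @export
print.coast_logistic_front <- function(x, ...) {
  cat("<coast_logistic_front>", x$form, "constants: N0 =", x$N0,
      ", K =", x$K, ", x_G =", x$x_G, "km\n")
  invisible(x)
}

#' Evaluate the stationary logistic front
#'
#' Evaluates the front of [stationary_logistic_profile()] at positions `x`.
#' The numerically stable decaying-exponential representation is used by
#' default; `representation = "growing"` evaluates the algebraically
#' identical form written with `exp(+x / x_G)` (it overflows for large `x`
#' and is retained for cross-checking the two spellings).
#'
#' @param x Distance from the coast, km (vectorised, non-negative).
#' @param profile A `"coast_logistic_front"` object.
#' @param representation `"decaying"` (default) or `"growing"`.
#' @return Dimensionless density (scaled back by `N_inf`), same length as
#'   `x`.
#' @export
stationary_profile <- function(x, profile,
                               representation = c("decaying", "growing")) {
  stopifnot(inherits(profile, "coast_logistic_front"))
  representation <- match.arg(representation)
  if (any(x < 0)) stop("`x` must be >= 0")
  K <- profile$K
  u <- if (representation == "decaying") {
    e <- exp(-x / profile$x_G)
    (1 - K * e) / (1 + K * e)
  } else {
    e <- exp(x / profile$x_G)
    # denominator e + K > 0 is guaranteed for K > -1 and x >= 0
    stopifnot(all(e + K > 0))
    (e - K) / (e + K)
  }
  n <- if (profile$form == "exact") 1.5 * u^2 - 0.5 else 3 * u^2 - 2
  n * profile$params$N_inf
}

#' Near-carrying-capacity approximation of the stationary front
#'
#' For a coastal value close to the carrying capacity (either side of it),
#' the front linearises to `N(x) ~ 1 - (1 - N0) exp(-x / x_G)`: a
#' transition zone of width `x_G` at the coast, carrying capacity further
#' inland.
#'
#' @inheritParams model1_density
#' @param params A [model_params()] with `r > 0`.
#' @return Dimensionless density (scaled by `N_inf`), same length as `x`.
#' @export
stationary_profile_approx <- function(x, params) {
  params <- as_coast_params(params)
  if (params$r <= 0) stop("`r` must be > 0")
  if (any(x < 0)) stop("`x` must be >= 0")
  n0 <- params$N0 / params$N_inf
  check_logistic_N0(n0)
  xg <- characteristic_length(params)
  (1 - (1 - n0) * exp(-x / xg)) * params$N_inf
}

#' Finite-difference residual oracle for the stationary front
#'
#' Evaluates the stationary logistic operator
#' `D N'' + r N (1 - N / N_inf)` by second-order central differences on a
#' uniform grid covering `[spacing, 20 x_G]` and returns the maximum
#' absolute residual (units 1/yr).  For the exact front the residual is
#' pure truncation error, far below `1e-6 * r`; for the printed-constant
#' front it equals `r (1 - N)^2 / 2` in magnitude, the fingerprint of the
#' equation that form actually solves.
#'
#' @param profile A `"coast_logistic_front"` object, or any function of `x`
#'   returning density (so perturbed profiles can be probed).
#' @param spacing Finite-difference step, km; must satisfy
#'   `spacing <= 1e-2 * x_G`.  When `profile` is a bare function, `params`
#'   must be supplied.
#' @param params Only used (and required) when `profile` is a function.
#' @return Maximum absolute residual in 1/yr.
#' @export
stationary_residual <- function(profile, spacing, params = NULL) {
  if (inherits(profile, "coast_logistic_front")) {
    params <- profile$params
    f <- function(x) stationary_profile(x, profile)
  } else if (is.function(profile)) {
    if (is.null(params)) stop("`params` required when `profile` is a function")
    params <- as_coast_params(params)
    f <- profile
  } else stop("`profile` must be a coast_logistic_front or a function")
  xg <- characteristic_length(params)
  if (spacing > 1e-2 * xg)
    stop("`spacing` must be <= 1e-2 * x_G for the residual oracle")
  x <- seq(spacing, 20 * xg, by = spacing)
  n <- f(x)
  lap <- (f(x + spacing) - 2 * n + f(x - spacing)) / spacing^2
  max(abs(params$D * lap + logistic_reaction(pmax(n, 0), params)))
}

#' Long-time limit of the non-spatial logistic model
#'
#' Integrates the plain logistic ordinary differential equation
#' `dN/dt = r N (1 - N / N_inf)` with the classical fourth-order
#' Runge-Kutta method and returns the terminal value.  From any positive
#' start below (or moderately above) carrying capacity the solution
#' approaches `N_inf`; this is the growth limit that the spatial logistic
#' model inherits pointwise far from the coast.
#'
#' @param N_init Initial density (positive); vectorised, all trajectories
#'   are integrated together.
#' @param params A [model_params()] with `r > 0`.
#' @param t_end Integration horizon, yr.
#' @param dt Runge-Kutta step, yr.
#' @return Terminal density value(s) at `t_end`.
#' @examples
#' logistic_ode_limit(0.5, model_params(r = 0.01), t_end = 5000)  # ~ 1
#' @export
logistic_ode_limit <- function(N_init, params, t_end = 5000, dt = 0.1) {
  params <- as_coast_params(params)
  if (params$r <= 0) stop("`r` must be > 0")
  if (any(N_init <= 0)) stop("`N_init` must be > 0")
  if (t_end <= 0 || dt <= 0) stop("`t_end` and `dt` must be > 0")
  f <- function(n) params$r * n * (1 - n / params$N_inf)
  nsteps <- ceiling(t_end / dt)
  h <- t_end / nsteps
  n <- N_init
  for (i in seq_len(nsteps)) {
    k1 <- f(n)
    k2 <- f(n + h / 2 * k1)
    k3 <- f(n + h / 2 * k2)
    k4 <- f(n + h * k3)
    n <- n + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  n
}
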
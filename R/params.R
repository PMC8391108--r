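#' Physical parameters of a growth-diffusion scenario
#'
#' Bundles the constants that define one scenario: the diffusion coefficient
#' `D` (km^2/yr), the growth rate `r` (1/yr, zero for the pure-diffusion
#' model), the coastal boundary density `N0` (dimensionless), and the
#' carrying-capacity scale `N_inf` used by the logistic model.  Densities are
#' dimensionless throughout, so integrated totals carry km units.
#'
#' @param D Diffusion coefficient in km^2/yr; must be positive.
#' @param r Growth rate in 1/yr; must be non-negative (zero disables growth).
#' @param N0 Coastal boundary density (dimensionless, non-negative).
#' @param N_inf Carrying-capacity scale for logistic growth; positive,
#'   default 1 (the normalised model).
#'
#' @return An object of class `"coast_params"`: a list with elements
#'   `D`, `r`, `N0`, `N_inf`.
#' @examples
#' p <- model_params(D = 1, r = 0.01)
#' characteristic_length(p)  # 10 km
#' @seealso [characteristic_length()], [calibrate_diffusion()]
#' @export
model_params <- function(D = 1, r = 0, N0 = 1, N_inf = 1) {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D),
            is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(N0), length(N0) == 1L, is.finite(N0),
            is.numeric(N_inf), length(N_inf) == 1L, is.finite(N_inf))
  if (D <= 0) stop("`D` must be > 0 (km^2/yr)")
  if (r < 0) stop("`r` must be >= 0 (1/yr)")
  if (N0 < 0) stop("`N0` must be >= 0")
  if (N_inf <= 0) stop("`N_inf` must be > 0")
  structure(list(D = D, r = r, N0 = N0, N_inf = N_inf),
            class = "coast_params")
}

#' @export
print.coast_params <- function(x, ...) {
  cat("<coast_params> D =", x$D, "km^2/yr, r =", x$r, "1/yr, N0 =", x$N0,
      ", N_inf =", x$N_inf, "\n")
  if (x$r > 0) cat("  characteristic length x_G =", sqrt(x$D / x$r), "km\n")
  invisible(x)
}

as_coast_params <- function(params) {
  if (inherits(params, "coast_params")) return(params)
  if (is.list(params)) return(do.call(model_params, params))
  stop("`params` must be a coast_params object (see model_params())")
}

#' Characteristic length scale of the growth-diffusion balance
#'
#' The single length scale `x_G = sqrt(D / r)` of the linear
#' growth-diffusion problem.  It sets the width of the coastal transition
#' zone of the logistic front and the existence window `L <= pi * x_G` of
#' the steady band waves.  Undefined when `r = 0`.
#'
#' @param params A [model_params()] object with `r > 0`.
#' @return Length in km.
#' @examples
#' characteristic_length(model_params(D = 1, r = 0.01))  # 10
#' @export
characteristic_length <- function(params) {
  params <- as_coast_params(params)
  if (params$r <= 0)
    stop("characteristic length x_G = sqrt(D/r) is undefined for r <= 0")
  sqrt(params$D / params$r)
}

#' Calibrate the diffusion coefficient from an observed spread
#'
#' Inverts the one-dimensional mean-square-displacement relation
#' `sigma^2 = 2 D t`: given that the city front has spread a distance
#' `sigma` (km) in time `t` (yr), returns `D = sigma^2 / (2 t)`.
#' With the reference calibration sigma = 10 km over t = 50 yr this gives
#' D = 1 km^2/yr.
#'
#' @param sigma Observed spread distance, km.
#' @param t Elapsed time, yr (positive).
#' @return Diffusion coefficient in km^2/yr.
#' @examples
#' calibrate_diffusion(10, 50)  # 1
#' @export
calibrate_diffusion <- function(sigma, t) {
  stopifnot(is.numeric(sigma), is.numeric(t))
  if (any(t <= 0)) stop("`t` must be > 0")
  sigma^2 / (2 * t)
}
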
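#' Uniform spatial grid on the truncated half-line
#'
#' A closed interval `[0, x_max]` discretised into `n_nodes` equally spaced
#' nodes, node 1 sitting on the coast at `x = 0`.  All fields and numerical
#' solutions in the package live on such grids.
#'
#' @param x_max Domain length in km (positive).
#' @param n_nodes Number of nodes (at least 2).  Exactly one of `n_nodes`
#'   and `spacing` must be given.
#' @param spacing Node spacing in km; if given, `n_nodes` is derived as
#'   `round(x_max / spacing) + 1` and the spacing is recomputed so the grid
#'   closes exactly at `x_max`.
#' @return An object of class `"coast_grid"` with elements `x_max`,
#'   `n_nodes`, `spacing`.
#' @examples
#' g <- spatial_grid(100, spacing = 0.1)
#' g$n_nodes  # 1001
#' @export
spatial_grid <- function(x_max, n_nodes = NULL, spacing = NULL) {
  stopifnot(is.numeric(x_max), length(x_max) == 1L, is.finite(x_max))
  if (x_max <= 0) stop("`x_max` must be > 0")
  if (is.null(n_nodes) == is.null(spacing))
    stop("give exactly one of `n_nodes` or `spacing`")
  if (is.null(n_nodes)) {
    if (spacing <= 0) stop("`spacing` must be > 0")
    n_nodes <- as.integer(round(x_max / spacing)) + 1L
  }
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 2L) stop("degenerate grid: need at least 2 nodes")
  structure(list(x_max = x_max, n_nodes = n_nodes,
                 spacing = x_max / (n_nodes - 1L)),
            class = "coast_grid")
}

#' Node coordinates of a grid
#' @param grid A [spatial_grid()].
#' @return Numeric vector of node positions in km, starting at 0.
#' @export
grid_nodes <- function(grid) {
  stopifnot(inherits(grid, "coast_grid"))
  seq(0, grid$x_max, length.out = grid$n_nodes)
}

#' @export
print.coast_grid <- function(x, ...) {
  cat("<coast_grid> [0,", x$x_max, "] km,", x$n_nodes, "nodes, spacing",
      x$spacing, "km\n")
  invisible(x)
}

#' Population-density profile on a grid at one time
#'
#' @param grid A [spatial_grid()].
#' @param values Dimensionless density at each node; finite and
#'   non-negative, one per node.
#' @param time Time stamp in yr.
#' @return An object of class `"coast_field"` with elements `grid`,
#'   `values`, `time`.
#' @export
density_field <- function(grid, values, time = 0) {
  stopifnot(inherits(grid, "coast_grid"), is.numeric(values),
            is.numeric(time), length(time) == 1L)
  if (length(values) != grid$n_nodes)
    stop("`values` must have one entry per grid node (",
         grid$n_nodes, ")")
  if (!all(is.finite(values))) stop("field values must be finite")
  if (any(values < 0)) stop("field values must be >= 0")
  structure(list(grid = grid, values = as.numeric(values), time = time),
            class = "coast_field")
}

#' @export
print.coast_field <- function(x, ...) {
  cat("<coast_field> t =", x$time, "yr on [0,", x$grid$x_max, "] km (",
      x$grid$n_nodes, "nodes); total =",
      format(integrate_field(x), digits = 6), "\n")
  invisible(x)
}

#' Total population of a density field
#'
#' Composite trapezoid integral of the density over its grid, the numerical
#' counterpart of the total urban population `N*(t)`.  Exact for fields
#' linear between nodes; `O(h^2)` otherwise.
#'
#' @param field A [density_field()].
#' @return Total population (dimensionless density times km).
#' @export
integrate_field <- function(field) {
  stopifnot(inherits(field, "coast_field"))
  trapz(field$grid$spacing, field$values)
}

# trapezoid rule on a uniform grid; h is the spacing
trapz <- function(h, y) {
  n <- length(y)
  if (n < 2L) stop("degenerate grid: need at least 2 nodes")
  h * (sum(y) - (y[1L] + y[n]) / 2)
}

#' Aggregate descriptors of a density field
#'
#' Normalises the field to the occupancy probability density
#' `p(x) = N(x) / N*` and returns the total population together with the
#' mean living location, the second moment, and the variance of `p`, all by
#' trapezoid quadrature on the field's grid.
#'
#' @param field A [density_field()] with strictly positive total.
#' @return An object of class `"coast_moments"`: list with `total`
#'   (density times km), `mean_x` (km), `second_moment` (km^2), `variance`
#'   (km^2).
#' @examples
#' g <- spatial_grid(100, spacing = 0.1)
#' f <- density_field(g, model1_density(grid_nodes(g), 100, model_params()),
#'                    time = 100)
#' field_moments(f)$variance / 100  # ~ 4/3 - pi/4
#' @export
field_moments <- function(field) {
  stopifnot(inherits(field, "coast_field"))
  total <- integrate_field(field)
  if (total <= 0) stop("empty population: field integrates to zero")
  x <- grid_nodes(field$grid)
  p <- field$values / total
  h <- field$grid$spacing
  mean_x <- trapz(h, x * p)
  second <- trapz(h, x^2 * p)
  structure(list(total = total, mean_x = mean_x, second_moment = second,
                 variance = second - mean_x^2),
            class = "coast_moments")
}

#' @export
print.coast_moments <- function(x, ...) {
  cat("<coast_moments> total =", format(x$total, digits = 6),
      "| mean_x =", format(x$mean_x, digits = 6), "km",
      "| var =", format(x$variance, digits = 6), "km^2\n")
  invisible(x)
}
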
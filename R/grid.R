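#' Uniform symmetric one-dimensional spatial grid
#'
#' All fields in the package live on a uniform grid over the symmetric
#' truncated domain \code{[-half_width, half_width]}.  The node count must be
#' odd so that \code{x = 0} is a node, which keeps symmetric habitat profiles
#' and initial conditions exactly representable.
#'
#' @param half_width Positive half-width of the domain (length units).
#' @param n_nodes Odd integer number of nodes, at least 65.
#' @return An object of class \code{"spatial_grid"} with elements
#'   \code{half_width}, \code{n_nodes}, \code{spacing} and \code{nodes}.
#' @examples
#' g <- spatial_grid(50, 1001)
#' g$spacing
#' @export
spatial_grid <- function(half_width, n_nodes = 2001) {
  if (!is.numeric(half_width) || length(half_width) != 1L || half_width <= 0)
    stop("'half_width' must be a single positive number", call. = FALSE)
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes != round(n_nodes))
    stop("'n_nodes' must be a single integer", call. = FALSE)
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 65L || n_nodes %% 2L == 0L)
    stop("'n_nodes' must be odd and at least 65 (so that x = 0 is a node)",
         call. = FALSE)
  spacing <- 2 * half_width / (n_nodes - 1L)
  nodes <- seq(-half_width, half_width, length.out = n_nodes)
  structure(
    list(half_width = half_width, n_nodes = n_nodes,
         spacing = spacing, nodes = nodes),
    class = "spatial_grid"
  )
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf("<spatial_grid> [-%g, %g], %d nodes, spacing %g\n",
              x$half_width, x$half_width, x$n_nodes, x$spacing))
  invisible(x)
}

is_spatial_grid <- function(x) inherits(x, "spatial_grid")

#' Nonnegative density field on a grid
#'
#' A per-location larval density sampled at the grid nodes.  Values must be
#' finite and nonnegative; small negative excursions within \code{-1e-12}
#' (solver round-off) are clipped to zero.
#'
#' @param grid A \code{\link{spatial_grid}}.
#' @param values Numeric vector of length \code{grid$n_nodes}, or a single
#'   number recycled to all nodes.
#' @return An object of class \code{"density_field"}.
#' @export
density_field <- function(grid, values) {
  if (!is_spatial_grid(grid)) stop("'grid' must be a spatial_grid", call. = FALSE)
  if (length(values) == 1L) values <- rep_len(as.numeric(values), grid$n_nodes)
  if (length(values) != grid$n_nodes)
    stop("'values' must have one entry per grid node", call. = FALSE)
  if (!all(is.finite(values)))
    stop("density values must all be finite", call. = FALSE)
  if (any(values < -1e-12))
    stop("density values must be nonnegative (beyond round-off slack 1e-12)",
         call. = FALSE)
  values[values < 0] <- 0
  structure(list(grid = grid, values = values), class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("<density_field> %d nodes, sup %g, mass %g\n",
              x$grid$n_nodes, field_sup(x), field_mass(x)))
  invisible(x)
}

#' Sup-norm of a density field
#' @param u A \code{\link{density_field}}.
#' @return Maximum nodal value.
#' @export
field_sup <- function(u) max(u$values)

#' Total mass of a density field (trapezoid rule)
#' @param u A \code{\link{density_field}}.
#' @return Trapezoid-rule integral of the field over the domain.
#' @export
field_mass <- function(u) {
  v <- u$values
  h <- u$grid$spacing
  h * (sum(v) - (v[1L] + v[length(v)]) / 2)
}
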
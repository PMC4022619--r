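# Planar geometry helpers shared by the io, habitat and synthetic modules.
# All coordinates are projected metres; polygons are lists with numeric `x`
# and `y` of equal length >= 3, open rings (first vertex not repeated).

abort_validation <- function(msg) {
  stop(structure(list(message = msg, call = NULL),
                 class = c("aguadas_validation_error", "error", "condition")))
}

abort_format <- function(msg) {
  stop(structure(list(message = msg, call = NULL),
                 class = c("aguadas_format_error", "error", "condition")))
}

abort_config <- function(msg) {
  stop(structure(list(message = msg, call = NULL),
                 class = c("aguadas_config_error", "error", "condition")))
}

is_ring <- function(p) {
  is.list(p) && all(c("x", "y") %in% names(p)) &&
    length(p$x) == length(p$y) && length(p$x) >= 3 &&
    all(is.finite(p$x)) && all(is.finite(p$y))
}

#' Polygon area (planar)
#'
#' Unsigned area of a simple polygon given as an open ring.
#'
#' @param poly list with numeric `x`, `y` (open ring, projected metres).
#' @return area in square metres.
#' @export
polygon_area <- function(poly) {
  if (!is_ring(poly)) abort_validation("polygon must have numeric x,y with >= 3 vertices")
  abs(pracma::polyarea(poly$x, poly$y))
}

# signed area; positive for counter-clockwise rings
polygon_signed_area <- function(poly) {
  x <- poly$x; y <- poly$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Polygon centroid (planar)
#'
#' Area-weighted centroid of a simple polygon.
#'
#' @inheritParams polygon_area
#' @return numeric length-2 vector `c(x, y)`.
#' @export
polygon_centroid <- function(poly) {
  if (!is_ring(poly)) abort_validation("polygon must have numeric x,y with >= 3 vertices")
  x <- poly$x; y <- poly$y
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a <- sum(cross) / 2
  if (abs(a) < .Machine$double.eps * max(abs(x), abs(y), 1)) {
    # degenerate ring: fall back to vertex mean
    return(c(mean(x), mean(y)))
  }
  cx <- sum((x + xn) * cross) / (6 * a)
  cy <- sum((y + yn) * cross) / (6 * a)
  c(cx, cy)
}

#' Point-in-polygon test
#'
#' Tests whether points fall inside a polygon. Points exactly on the boundary
#' (edge or vertex) count as inside.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param poly polygon as an open ring (`x`, `y`).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  if (!is_ring(poly)) abort_validation("polygon must have numeric x,y with >= 3 vertices")
  sp::point.in.polygon(px, py, poly$x, poly$y) > 0
}

#' Regular-polygon approximation of a circle
#'
#' @param cx,cy centre coordinates (m).
#' @param r radius (m), `r >= 0`.
#' @param n_segments number of vertices (default 128).
#' @return polygon as an open counter-clockwise ring.
#' @export
circle_polygon <- function(cx, cy, r, n_segments = 128L) {
  if (!is.finite(r) || r < 0) abort_validation("radius must be finite and >= 0")
  theta <- seq(0, 2 * pi, length.out = n_segments + 1L)[-(n_segments + 1L)]
  list(x = cx + r * cos(theta), y = cy + r * sin(theta))
}

# rectangle ring (counter-clockwise)
rect_polygon <- function(xmin, ymin, xmax, ymax) {
  list(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}
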
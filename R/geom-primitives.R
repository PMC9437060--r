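# Planar geometry primitives used throughout the package.
#
# All coordinates are local Cartesian metres on a flat plane; polygons are
# two-column (x, y) matrices, implicitly closed (last vertex joins the first).

#' Test points for inclusion in a planar polygon
#'
#' Even-odd (ray casting) point-in-polygon test with points lying on the
#' polygon boundary counted as inside, so that closed regions behave as
#' closed sets.
#'
#' @param px,py Numeric vectors of point coordinates (metres).
#' @param poly Two-column matrix of polygon vertices (implicitly closed).
#' @param boundary_eps Distance below which a point counts as on the boundary.
#' @return Logical vector, one entry per point.
#' @export
points_in_polygon <- function(px, py, poly, boundary_eps = 1e-9) {
  stopifnot(length(px) == length(py), is.matrix(poly), ncol(poly) == 2)
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    on_edge <- on_edge | (point_segment_distance(px, py, xi, yi, xj, yj) <= boundary_eps)
    j <- i
  }
  inside | on_edge
}

#' Distance from points to a line segment
#'
#' @param px,py Point coordinates (vectorized).
#' @param ax,ay,bx,by Segment endpoints (scalars).
#' @return Numeric vector of Euclidean distances.
#' @keywords internal
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / len2))
  sqrt((px - ax - t * dx)^2 + (py - ay - t * dy)^2)
}

# Intersection of a directed path p0 -> p1 with segment a -> b.
# Returns the path parameter u in [0, 1] at the crossing, or NA if none.
segment_crossing_param <- function(p0x, p0y, p1x, p1y, ax, ay, bx, by) {
  rx <- p1x - p0x; ry <- p1y - p0y
  sx <- bx - ax;  sy <- by - ay
  denom <- rx * sy - ry * sx
  if (abs(denom) < 1e-300) return(NA_real_)
  qx <- ax - p0x; qy <- ay - p0y
  u <- (qx * sy - qy * sx) / denom   # along path
  v <- (qx * ry - qy * rx) / denom   # along edge
  if (u >= 0 && u <= 1 && v >= -1e-12 && v <= 1 + 1e-12) u else NA_real_
}

#' Regular polygon approximating a circle
#'
#' @param centre Length-2 numeric (x, y) in metres.
#' @param radius Radius in metres.
#' @param n Number of vertices.
#' @return Two-column vertex matrix.
#' @keywords internal
circle_polygon <- function(centre, radius, n = 28) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(centre[1] + radius * cos(th), centre[2] + radius * sin(th))
}

# Cumulative arc length along a polyline (two-column matrix).
polyline_cumlength <- function(pl) {
  d <- sqrt(diff(pl[, 1])^2 + diff(pl[, 2])^2)
  c(0, cumsum(d))
}

# Point at arc length s along a polyline.
polyline_point_at <- function(pl, s) {
  cl <- polyline_cumlength(pl)
  s <- min(max(s, 0), cl[length(cl)])
  i <- max(which(cl <= s + 1e-12))
  if (i >= nrow(pl)) return(pl[nrow(pl), ])
  seg_len <- cl[i + 1] - cl[i]
  f <- if (seg_len > 0) (s - cl[i]) / seg_len else 0
  pl[i, ] + f * (pl[i + 1, ] - pl[i, ])
}

# Arc length of the projection of point (px, py) onto a polyline,
# taken at the polyline vertex-edge of minimum distance.
polyline_project <- function(pl, px, py) {
  cl <- polyline_cumlength(pl)
  best_d <- Inf; best_s <- 0
  for (i in seq_len(nrow(pl) - 1)) {
    ax <- pl[i, 1]; ay <- pl[i, 2]; bx <- pl[i + 1, 1]; by <- pl[i + 1, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 > 0) min(1, max(0, ((px - ax) * dx + (py - ay) * dy) / len2)) else 0
    d <- sqrt((px - ax - t * dx)^2 + (py - ay - t * dy)^2)
    if (d < best_d) {
      best_d <- d
      best_s <- cl[i] + t * sqrt(len2)
    }
  }
  list(s = best_s, distance = best_d)
}
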
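# Planar geometry helpers. All coordinates are kilometres in a local
# projection supplied by the caller; no geodetic math is performed.

#' Distance from points to a set of segments
#'
#' @param x,y numeric vectors of point coordinates (km).
#' @param seg matrix with columns ax, ay, bx, by (one segment per row).
#' @return numeric vector of minimum distances.
#' @keywords internal
dist_to_segments <- function(x, y, seg) {
  stopifnot(ncol(seg) == 4L)
  n <- length(x)
  out <- rep(Inf, n)
  for (k in seq_len(nrow(seg))) {
    ax <- seg[k, 1]; ay <- seg[k, 2]; bx <- seg[k, 3]; by <- seg[k, 4]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d <- sqrt((x - ax)^2 + (y - ay)^2)
    } else {
      t <- pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / len2))
      d <- sqrt((x - ax - t * dx)^2 + (y - ay - t * dy)^2)
    }
    out <- pmin(out, d)
  }
  out
}

polygon_segments <- function(poly) {
  # poly: n x 2 matrix of vertices (closed implicitly)
  p2 <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE])
  cbind(poly[, 1], poly[, 2], p2[, 1], p2[, 2])
}

polyline_segments <- function(line) {
  n <- nrow(line)
  if (n < 2L) stop("polyline needs >= 2 vertices")
  cbind(line[-n, 1], line[-n, 2], line[-1, 1], line[-1, 2])
}

#' Point membership in any polygon of a set
#'
#' Boundary points count as inside (deterministic tie-break).
#' @param x,y point coordinates; @param polys list of n x 2 vertex matrices.
#' @keywords internal
in_any_polygon <- function(x, y, polys) {
  inside <- rep(FALSE, length(x))
  for (p in polys) {
    hit <- sp::point.in.polygon(x, y, p[, 1], p[, 2]) > 0
    inside <- inside | hit
  }
  inside
}

#' Distance from points to the nearest polygon of a set (0 when inside)
#' @keywords internal
dist_to_polygons <- function(x, y, polys) {
  d <- rep(Inf, length(x))
  for (p in polys) {
    d <- pmin(d, dist_to_segments(x, y, polygon_segments(p)))
  }
  d[in_any_polygon(x, y, polys)] <- 0
  d
}

#' Distance from points to the nearest polyline of a set
#' @keywords internal
dist_to_polylines <- function(x, y, lines) {
  d <- rep(Inf, length(x))
  for (l in lines) {
    d <- pmin(d, dist_to_segments(x, y, polyline_segments(l)))
  }
  d
}

#' Maximum pairwise distance between locations
#'
#' The largest dimension of a ranging area: the longest Euclidean distance
#' between any two locations. Returns 0 for a single point.
#'
#' @param points matrix or data.frame with columns x, y (km).
#' @return distance in km.
#' @export
max_distance <- function(points) {
  pts <- as.matrix(points[, c("x", "y"), drop = FALSE])
  storage.mode(pts) <- "double"
  if (nrow(pts) == 0L) stop("no points supplied")
  if (nrow(pts) == 1L) return(0)
  max(stats::dist(pts))
}
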
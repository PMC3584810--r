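# Geometric kernels shared by the model, trait and soil modules.
# All coordinates in cm; y grows downward (depth).

#' Per-segment lengths of a polyline
#'
#' @param polyline numeric matrix with columns x, y (diameter column ignored).
#' @return numeric vector of length `nrow(polyline) - 1` (or numeric(0) for a
#'   single node).
#' @export
segmentLengths <- function(polyline) {
  n <- nrow(polyline)
  if (n < 2L) return(numeric(0))
  sqrt(diff(polyline[, "x"])^2 + diff(polyline[, "y"])^2)
}

#' Total arc length of a polyline
#' @inheritParams segmentLengths
#' @export
polylineLength <- function(polyline) sum(segmentLengths(polyline))

#' Cumulative arc-length positions of polyline nodes
#' @inheritParams segmentLengths
#' @return numeric vector, one entry per node, starting at 0.
#' @export
arcPositions <- function(polyline) c(0, cumsum(segmentLengths(polyline)))

#' Nearest point on a polyline
#'
#' Projects a query point onto every segment of the polyline (clamping to the
#' segment ends) and returns the arc-length position of the overall closest
#' point, measured from the first node, together with the euclidean distance
#' to it. For a single-node polyline the arc length is 0. Ties in distance
#' are resolved toward the smallest arc length.
#'
#' @param polyline numeric matrix with columns x, y (>= 1 row).
#' @param point numeric(2): (x, y) in cm.
#' @return numeric(2): `c(arc, distance)` in cm.
#' @examples
#' pl <- cbind(x = c(0, 0), y = c(0, 10), diameter = 0.1)
#' nearestOnPolyline(pl, c(1, 4))   # arc 4, distance 1
#' nearestOnPolyline(pl, c(3, 14))  # clamped to the tip: arc 10, distance 5
#' @export
nearestOnPolyline <- function(polyline, point) {
  if (is.null(dim(polyline)) || nrow(polyline) < 1L)
    stop("polyline must have at least one node")
  px <- unname(point[1]); py <- unname(point[2])
  x <- polyline[, "x"]; y <- polyline[, "y"]
  n <- length(x)
  if (n == 1L)
    return(c(arc = 0, distance = unname(sqrt((px - x)^2 + (py - y)^2))))
  dx <- diff(x); dy <- diff(y)
  len2 <- dx^2 + dy^2
  # parameter of the orthogonal projection, clamped to [0, 1]; degenerate
  # (zero-length) segments collapse to their first node
  t <- ifelse(len2 > 0, ((px - x[-n]) * dx + (py - y[-n]) * dy) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  cx <- x[-n] + t * dx
  cy <- y[-n] + t * dy
  d <- sqrt((px - cx)^2 + (py - cy)^2)
  arcs <- arcPositions(polyline)
  cand <- arcs[-n] + t * sqrt(len2)
  best <- which(d <= min(d) + 0e0)  # exact min; ties -> smallest arc
  i <- best[which.min(cand[best])]
  c(arc = unname(cand[i]), distance = unname(d[i]))
}

#' Point on a polyline at a given arc length
#'
#' Linear interpolation along the polyline; positions outside `[0, L]` are
#' clamped to the ends.
#'
#' @inheritParams segmentLengths
#' @param arc arc-length position (cm).
#' @return numeric(2): (x, y).
#' @export
pointAtArc <- function(polyline, arc) {
  arcs <- arcPositions(polyline)
  L <- arcs[length(arcs)]
  a <- min(max(arc, 0), L)
  if (nrow(polyline) == 1L || L == 0)
    return(unname(c(polyline[1, "x"], polyline[1, "y"])))
  i <- findInterval(a, arcs, rightmost.closed = TRUE)
  i <- min(i, nrow(polyline) - 1L)
  seg <- arcs[i + 1L] - arcs[i]
  t <- if (seg > 0) (a - arcs[i]) / seg else 0
  unname(c(polyline[i, "x"] + t * (polyline[i + 1L, "x"] - polyline[i, "x"]),
           polyline[i, "y"] + t * (polyline[i + 1L, "y"] - polyline[i, "y"])))
}

#' Length, surface and volume of one root segment
#'
#' The segment between two traced nodes is treated as a conical frustum with
#' end diameters `d1`, `d2`: length is the euclidean node distance, lateral
#' surface uses the mean-diameter cylinder `pi * (d1 + d2)/2 * L` (no slant
#' correction; per-segment taper is small), and volume is the exact frustum
#' `pi/12 * L * (d1^2 + d1*d2 + d2^2)`.
#'
#' @param n1,n2 numeric vectors `c(x, y, diameter)` in cm.
#' @return named numeric(3): length (cm), surface (cm^2), volume (cm^3).
#' @examples
#' segmentMeasures(c(0, 0, 0.1), c(3, 4, 0.1))  # length 5, surface 0.5*pi
#' @export
segmentMeasures <- function(n1, n2) {
  n1 <- unname(n1); n2 <- unname(n2)
  d1 <- n1[3]; d2 <- n2[3]
  if (d1 < 0 || d2 < 0) stop("negative diameter")
  L <- sqrt((n2[1] - n1[1])^2 + (n2[2] - n1[2])^2)
  c(length = L,
    surface = pi * (d1 + d2) / 2 * L,
    volume = pi / 12 * L * (d1^2 + d1 * d2 + d2^2))
}

# Per-segment measures for a whole polyline: matrix with columns
# length, surface, volume, projected (projected area = mean diameter * length).
.polylineMeasures <- function(polyline) {
  n <- nrow(polyline)
  if (n < 2L)
    return(matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("length", "surface", "volume",
                                          "projected"))))
  L <- segmentLengths(polyline)
  d1 <- polyline[-n, "diameter"]; d2 <- polyline[-1, "diameter"]
  cbind(length = L,
        surface = pi * (d1 + d2) / 2 * L,
        volume = pi / 12 * L * (d1^2 + d1 * d2 + d2^2),
        projected = (d1 + d2) / 2 * L)
}

# Distances from many points to one segment (vectorized over points).
.pointsToSegment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx^2 + dy^2
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / len2, 0), 1)
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# Minimum distance from many points to all segments of a polyline.
.pointsToPolyline <- function(px, py, polyline) {
  n <- nrow(polyline)
  if (n == 1L)
    return(sqrt((px - polyline[1, "x"])^2 + (py - polyline[1, "y"])^2))
  best <- rep(Inf, length(px))
  for (i in seq_len(n - 1L)) {
    d <- .pointsToSegment(px, py, polyline[i, "x"], polyline[i, "y"],
                          polyline[i + 1L, "x"], polyline[i + 1L, "y"])
    best <- pmin(best, d)
  }
  best
}
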
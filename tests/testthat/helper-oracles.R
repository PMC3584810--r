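# Independent oracles, kept deliberately different in formulation from the
# package implementation.

# nearest point on a polyline by dense sampling at `step` cm
sampledNearest <- function(polyline, point, step = 1e-4) {
  arcs <- c(0, cumsum(sqrt(diff(polyline[, "x"])^2 +
                           diff(polyline[, "y"])^2)))
  L <- arcs[length(arcs)]
  s <- seq(0, L, by = step)
  xs <- approx(arcs, polyline[, "x"], xout = s)$y
  ys <- approx(arcs, polyline[, "y"], xout = s)$y
  d <- sqrt((xs - point[1])^2 + (ys - point[2])^2)
  i <- which.min(d)
  c(arc = s[i], distance = d[i])
}

# point-segment distance by exact minimization of the quadratic
# |p - (a + t(b-a))|^2 in t; vectorized over query points
quadSegDist <- function(px, py, ax, ay, bx, by) {
  ux <- unname(bx - ax); uy <- unname(by - ay)
  qa <- ux^2 + uy^2
  if (qa == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  qb <- 2 * ((ax - px) * ux + (ay - py) * uy)
  tstar <- pmax(0, pmin(1, -qb / (2 * qa)))
  sqrt((ax + tstar * ux - px)^2 + (ay + tstar * uy - py)^2)
}

# brute-force distance map: enumerate every segment of every root into a
# (pixel x segment) distance matrix, then take the row minimum
bruteDistanceGrid <- function(system, nrow, ncol, origin, h) {
  px <- rep(origin[1] + (seq_len(ncol) - 0.5) * h, each = nrow)
  py <- rep(origin[2] + (seq_len(nrow) - 0.5) * h, times = ncol)
  cols <- list()
  for (r in system@roots) {
    pl <- r@polyline
    if (nrow(pl) == 1L) {
      cols[[length(cols) + 1L]] <-
        sqrt((px - pl[1, "x"])^2 + (py - pl[1, "y"])^2)
    } else {
      for (k in seq_len(nrow(pl) - 1L))
        cols[[length(cols) + 1L]] <-
          quadSegDist(px, py, pl[k, "x"], pl[k, "y"],
                      pl[k + 1L, "x"], pl[k + 1L, "y"])
    }
  }
  allSeg <- do.call(cbind, cols)
  matrix(apply(allSeg, 1, min), nrow, ncol)
}

# frustum measures recomputed from scratch (integral forms)
oracleSegMeasure <- function(x1, y1, d1, x2, y2, d2, measure) {
  L <- unname(sqrt((x2 - x1)^2 + (y2 - y1)^2))
  d1 <- unname(d1); d2 <- unname(d2)
  switch(measure,
         length = L,
         surface = pi * L * (d1 + d2) / 2,
         volume = pi * L * (d1^2 + d1 * d2 + d2^2) / 12)
}

# exhaustive tipward enumeration for the distal cumulative measure:
# walks every root of the subtree explicitly, splitting the query root's
# polyline at the query arc by linear interpolation
bruteDistal <- function(system, rootId, pos, measure) {
  total <- 0
  addWhole <- function(id) {
    pl <- system@roots[[id]]@polyline
    if (nrow(pl) >= 2L)
      for (k in seq_len(nrow(pl) - 1L))
        total <<- total + oracleSegMeasure(
          pl[k, "x"], pl[k, "y"], pl[k, "diameter"],
          pl[k + 1, "x"], pl[k + 1, "y"], pl[k + 1, "diameter"], measure)
    for (cid in childIds(system, id)) addWhole(cid)
  }
  pl <- system@roots[[rootId]]@polyline
  arcs <- c(0, cumsum(sqrt(diff(pl[, "x"])^2 + diff(pl[, "y"])^2)))
  if (nrow(pl) >= 2L) for (k in seq_len(nrow(pl) - 1L)) {
    a0 <- arcs[k]; a1 <- arcs[k + 1]
    if (a1 <= pos || a1 == a0) next
    f <- max(0, min(1, (pos - a0) / (a1 - a0)))
    xs <- pl[k, "x"] + f * (pl[k + 1, "x"] - pl[k, "x"])
    ys <- pl[k, "y"] + f * (pl[k + 1, "y"] - pl[k, "y"])
    ds <- pl[k, "diameter"] + f * (pl[k + 1, "diameter"] - pl[k, "diameter"])
    total <- total + oracleSegMeasure(xs, ys, ds, pl[k + 1, "x"],
                                      pl[k + 1, "y"], pl[k + 1, "diameter"],
                                      measure)
  }
  for (cid in childIds(system, rootId))
    if (system@roots[[cid]]@insertion >= pos) addWhole(cid)
  total
}

# Fitter indices via an explicit link graph and igraph longest-path search
igraphFitter <- function(system, baseId) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  edges <- character(0)
  tips <- character(0)
  build <- function(id, baseNode) {
    kids <- childIds(system, id)
    pos <- vapply(kids, function(k) system@roots[[k]]@insertion, numeric(1))
    kids <- kids[order(pos, kids)]
    pos <- sort(pos)
    prev <- baseNode
    for (u in unique(pos)) {
      node <- paste0(id, "@", u)
      edges <<- c(edges, prev, node)
      prev <- node
      for (k in kids[pos == u]) build(k, node)
    }
    tip <- paste0(id, "@tip")
    edges <<- c(edges, prev, tip)
    tips <<- c(tips, tip)
  }
  build(baseId, "BASE")
  g <- igraph::make_graph(edges, directed = FALSE)
  d <- igraph::distances(g, v = "BASE", to = tips)
  list(magnitude = length(tips), altitude = max(d),
       exteriorPathLength = sum(d))
}
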
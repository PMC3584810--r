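# Crossing root architecture with raster soil-water maps: grid
# downsampling, nearest-segment distance maps, the soil x root long table
# and distance-binned time series.

# normalize a geometry argument: a SoilGrid, a DistanceMap, or a list with
# nrow, ncol, origin, pixelSize
.gridGeometry <- function(geometry) {
  if (is(geometry, "SoilGrid"))
    return(list(nrow = nrow(geometry@values), ncol = ncol(geometry@values),
                origin = geometry@origin, pixelSize = geometry@pixelSize))
  if (is(geometry, "DistanceMap"))
    return(list(nrow = nrow(geometry@distance), ncol = ncol(geometry@distance),
                origin = geometry@origin, pixelSize = geometry@pixelSize))
  need <- c("nrow", "ncol", "origin", "pixelSize")
  if (!is.list(geometry) || !all(need %in% names(geometry)))
    stop("geometry must be a SoilGrid, a DistanceMap, or a list with ",
         paste(need, collapse = ", "))
  geometry
}

#' Downsample a soil grid by block averaging
#'
#' Reduces a grid to a coarser pixel size that must be an exact integer
#' multiple of the source pixel size, by taking the mean over each k x k
#' block (which conserves the global mean exactly). The canonical use is
#' reducing a high-resolution transmission image of a 50 x 50 cm rhizotron
#' to a 50 x 50 pixel map with 1 cm^2 pixels.
#'
#' @param grid a [SoilGrid].
#' @param targetPixel desired pixel size in cm.
#' @return a [SoilGrid] with the same origin and timestamp.
#' @export
downsampleGrid <- function(grid, targetPixel) {
  k <- targetPixel / grid@pixelSize
  if (abs(k - round(k)) > 1e-9)
    stop("resampling error: target pixel ", targetPixel,
         " is not an integer multiple of the source pixel ", grid@pixelSize)
  k <- as.integer(round(k))
  nr <- nrow(grid@values); nc <- ncol(grid@values)
  if (nr %% k != 0L || nc %% k != 0L)
    stop("resampling error: grid dimensions ", nr, " x ", nc,
         " are not divisible by the block factor ", k)
  if (k == 1L) return(grid)
  v <- grid@values
  # k x k block means: sum rows within blocks, then columns, divide by k^2
  v <- rowsum(v, (seq_len(nr) - 1L) %/% k)
  v <- t(rowsum(t(v), (seq_len(nc) - 1L) %/% k)) / k^2
  dimnames(v) <- NULL
  SoilGrid(v, origin = grid@origin, pixelSize = targetPixel,
           timestamp = grid@timestamp)
}

#' Distance map to the nearest root segment
#'
#' For every pixel center of the given grid geometry, computes the minimum
#' euclidean distance to any root segment (full point-to-segment distance
#' to the root centerline) and records the id and order of the root owning
#' the nearest segment. Ties between roots are broken by the
#' lexicographically smallest root id. Single-node roots are treated as
#' points.
#'
#' @param system a [RootSystem] with at least one root.
#' @param geometry a [SoilGrid], [DistanceMap] or
#'   `list(nrow, ncol, origin, pixelSize)`.
#' @return a [DistanceMap].
#' @export
distanceMap <- function(system, geometry) {
  if (!length(system@roots)) stop("empty system: no roots to measure against")
  geo <- .gridGeometry(geometry)
  nr <- geo$nrow; nc <- geo$ncol
  # pixel centers, column-major to match matrix filling
  cx <- geo$origin[1] + (seq_len(nc) - 0.5) * geo$pixelSize
  cy <- geo$origin[2] + (seq_len(nr) - 0.5) * geo$pixelSize
  px <- rep(cx, each = nr)
  py <- rep(cy, times = nc)
  best <- rep(Inf, nr * nc)
  bestId <- rep(NA_character_, nr * nc)
  bestOrd <- rep(NA_integer_, nr * nc)
  for (id in sort(names(system@roots))) {
    r <- system@roots[[id]]
    d <- .pointsToPolyline(px, py, r@polyline)
    upd <- d < best  # strict: earlier (smaller) id wins exact ties
    best[upd] <- d[upd]
    bestId[upd] <- id
    bestOrd[upd] <- r@order
  }
  new("DistanceMap",
      distance = matrix(best, nr, nc),
      nearestId = matrix(bestId, nr, nc),
      nearestOrder = matrix(bestOrd, nr, nc),
      origin = as.numeric(geo$origin), pixelSize = as.numeric(geo$pixelSize))
}

#' Merge a soil grid series with a distance map
#'
#' Builds the long-format soil x root table: one row per (pixel, timestamp)
#' carrying the pixel's water content at that time together with the
#' time-invariant distance to, and identity/order of, its nearest root
#' (root growth over the observation window is assumed negligible).
#'
#' @param series list of [SoilGrid] sharing the [DistanceMap] geometry.
#' @param dmap a [DistanceMap].
#' @return data.frame with columns `row`, `col`, `x_cm`, `y_cm`, `time_h`,
#'   `water_content`, `distance_cm`, `nearest_root`, `nearest_order`;
#'   `pixels x timestamps` rows.
#' @export
joinSoilRoot <- function(series, dmap) {
  if (!length(series)) stop("join error: empty grid series")
  nr <- nrow(dmap@distance); nc <- ncol(dmap@distance)
  for (g in series) {
    if (nrow(g@values) != nr || ncol(g@values) != nc ||
        any(abs(g@origin - dmap@origin) > 1e-9) ||
        abs(g@pixelSize - dmap@pixelSize) > 1e-9)
      stop("join error: grid at t = ", g@timestamp,
           " h does not match the distance-map geometry")
  }
  idx <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  ij <- cbind(idx$row, idx$col)
  perTime <- lapply(series, function(g) data.frame(
    row = idx$row, col = idx$col,
    x_cm = dmap@origin[1] + (idx$col - 0.5) * dmap@pixelSize,
    y_cm = dmap@origin[2] + (idx$row - 0.5) * dmap@pixelSize,
    time_h = g@timestamp,
    water_content = g@values[ij],
    distance_cm = dmap@distance[ij],
    nearest_root = dmap@nearestId[ij],
    nearest_order = dmap@nearestOrder[ij],
    stringsAsFactors = FALSE))
  do.call(rbind, c(perTime, list(make.row.names = FALSE)))
}

#' Distance-binned water-content time series
#'
#' Aggregates the soil x root table into mean water content and pixel count
#' per (timestamp, distance bin). Bins are half-open `[e_i, e_{i+1})` over
#' the supplied strictly increasing edges (default 0..15 cm in 1 cm steps,
#' the range over which water depletion around roots is typically resolved
#' in a rhizotron); distances at or beyond the last edge fall into an
#' overflow bin. The n-weighted mean over bins reproduces each timestamp's
#' global mean exactly.
#'
#' @param table data.frame from [joinSoilRoot()].
#' @param binEdges strictly increasing numeric vector of bin edges (cm).
#' @return data.frame with columns `time_h`, `bin`, `dist_lo`, `dist_hi`,
#'   `mean_distance_cm`, `mean_water_content`, `n`.
#' @export
distanceBinnedSeries <- function(table, binEdges = 0:15) {
  if (!nrow(table)) stop("aggregation error: empty table")
  if (length(binEdges) < 2L || any(diff(binEdges) <= 0))
    stop("bin edges must be strictly increasing")
  edges <- c(binEdges, Inf)
  bin <- cut(table$distance_cm, breaks = edges, right = FALSE,
             include.lowest = FALSE)
  keep <- !is.na(bin)  # distances below the first edge (if any) are dropped
  tb <- table[keep, ]
  bin <- bin[keep]
  key <- interaction(tb$time_h, bin, drop = TRUE)
  agg <- data.frame(
    time_h = tapply(tb$time_h, key, `[`, 1L),
    bin = tapply(as.character(bin), key, `[`, 1L),
    mean_distance_cm = tapply(tb$distance_cm, key, mean),
    mean_water_content = tapply(tb$water_content, key, mean),
    n = as.integer(tapply(tb$water_content, key, length)),
    stringsAsFactors = FALSE)
  lv <- levels(bin)
  lohi <- regmatches(agg$bin, gregexpr("[0-9.eE+-]+|Inf", agg$bin))
  agg$dist_lo <- vapply(lohi, function(p) as.numeric(p[1]), numeric(1))
  agg$dist_hi <- vapply(lohi, function(p) as.numeric(p[2]), numeric(1))
  agg <- agg[order(agg$time_h, agg$dist_lo),
             c("time_h", "bin", "dist_lo", "dist_hi", "mean_distance_cm",
               "mean_water_content", "n")]
  rownames(agg) <- NULL
  agg
}

#' Fit an exponential depletion profile to binned water content
#'
#' Fits `W(d) = W0 - A * exp(-d / ell)` by nonlinear least squares to the
#' per-bin mean water contents of one timestamp, using each bin's mean
#' distance as the abscissa and its pixel count as weight. This recovers
#' the depletion length scale `ell` (cm) describing how far the
#' water-content draw-down around roots extends.
#'
#' @param binned data.frame from [distanceBinnedSeries()].
#' @param time timestamp (hours) to fit; must exist in `binned`.
#' @return named numeric: `W0`, `A`, `ell`.
#' @export
fitDepletionProfile <- function(binned, time) {
  df <- binned[binned$time_h == time, ]
  if (nrow(df) < 4L)
    stop("need at least 4 distance bins at t = ", time, " h to fit")
  w <- df$mean_water_content
  d <- df$mean_distance_cm
  start <- list(W0 = max(w), A = max(w) - min(w) + 1e-3,
                ell = max(d[2], 1))
  fit <- minpack.lm::nlsLM(w ~ W0 - A * exp(-d / ell), start = start,
                           weights = df$n,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  out <- stats::coef(fit)
  c(W0 = unname(out["W0"]), A = unname(out["A"]), ell = unname(out["ell"]))
}
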
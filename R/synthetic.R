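# Seeded generators: maize-like root systems, their split into partial
# tracings, binary mask rendering, and water-depletion map series. These are
# first-class fixtures: every downstream stage can be exercised against
# ground truth they carry.

#' Architecture generator parameters
#'
#' Defaults emulate the root system of a 20-day old maize plant in a
#' 50 x 50 cm rhizotron: one primary axis, 2-3 seminal and 2-4 adventitious
#' axes (so 5-8 first-order axes in total), with up to third-order laterals.
#' Axes grow as a stepwise heading random walk pulled toward the vertical
#' (gravitropism), laterals arise as a Poisson process along their parent
#' outside an apical unbranched zone, and diameters decrease with order and
#' taper toward the tip.
#'
#' @param nPrimary number of primary axes (default 1; the seminal count
#'   below does not include it).
#' @param seminalRange inclusive range for the seminal axis count.
#' @param adventitiousRange inclusive range for the adventitious axis count.
#' @param stepLength growth step (cm) of the heading random walk.
#' @param gravitropism per-order fraction of the angle to vertical removed
#'   at each step, in [0, 1]; axes are strongly gravitropic, laterals barely.
#' @param headingNoiseSd per-order heading noise (degrees per step).
#' @param lateralDensity branching rate (laterals per cm) on order-1 and
#'   order-2 parents.
#' @param apicalZone unbranched apical zone (cm) on order-1 and order-2
#'   parents.
#' @param baseDiameter per-order basal diameter (cm); per-root values are
#'   jittered by +-10%.
#' @param taper fraction of the basal diameter lost linearly by the tip.
#' @param axisLengthFrac range of order-1 target lengths as a fraction of
#'   the rhizotron depth.
#' @param lateralLengthRange list of length-2 ranges (cm) for order-2 and
#'   order-3 root target lengths.
#' @param branchAngle range (degrees) of the insertion angle of a lateral
#'   relative to its parent's local direction.
#' @param maxOrder deepest branching order (<= 3).
#' @param extent rhizotron width and height (cm).
#' @return a named list of class `ArchitectureParams`.
#' @export
architectureParams <- function(nPrimary = 1L,
                               seminalRange = c(2L, 3L),
                               adventitiousRange = c(2L, 4L),
                               stepLength = 0.5,
                               gravitropism = c(0.25, 0.08, 0.02),
                               headingNoiseSd = c(8, 18, 25),
                               lateralDensity = c(0.6, 0.2),
                               apicalZone = c(4, 1.5),
                               baseDiameter = c(0.45, 0.15, 0.08),
                               taper = 0.2,
                               axisLengthFrac = c(0.6, 1.05),
                               lateralLengthRange = list(c(2, 10), c(0.5, 2.5)),
                               branchAngle = c(45, 80),
                               maxOrder = 3L,
                               extent = c(50, 50)) {
  p <- list(nPrimary = as.integer(nPrimary),
            seminalRange = as.integer(seminalRange),
            adventitiousRange = as.integer(adventitiousRange),
            stepLength = stepLength, gravitropism = gravitropism,
            headingNoiseSd = headingNoiseSd,
            lateralDensity = lateralDensity, apicalZone = apicalZone,
            baseDiameter = baseDiameter, taper = taper,
            axisLengthFrac = axisLengthFrac,
            lateralLengthRange = lateralLengthRange,
            branchAngle = branchAngle, maxOrder = as.integer(maxOrder),
            extent = extent)
  stopifnot(p$stepLength > 0, p$maxOrder >= 1L, p$maxOrder <= 3L,
            all(diff(p$seminalRange) >= 0),
            all(diff(p$adventitiousRange) >= 0),
            all(p$gravitropism >= 0 & p$gravitropism <= 1),
            all(p$extent > 0), p$taper >= 0, p$taper < 1)
  class(p) <- "ArchitectureParams"
  p
}

# run code under a seeded local RNG, restoring the caller's stream
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# clamp a point into [0, w] x [0, h]
.clampPoint <- function(p, extent) {
  c(min(max(p[1], 0), extent[1]), min(max(p[2], 0), extent[2]))
}

# grow one root as a heading random walk. theta is the angle from the
# vertical-down direction, in radians; direction = (sin theta, cos theta).
# Stops at the target length or when clamped at the rhizotron boundary.
.growPolyline <- function(start, theta, g, noiseSd, target, step, extent,
                          d0, taper) {
  pts <- matrix(start, 1, 2)
  len <- 0
  noiseRad <- noiseSd * pi / 180
  while (len < target) {
    theta <- theta * (1 - g) + stats::rnorm(1, 0, noiseRad)
    s <- min(step, target - len)
    if (s < 1e-9) break
    nxt <- pts[nrow(pts), ] + s * c(sin(theta), cos(theta))
    clamped <- .clampPoint(nxt, extent)
    moved <- sqrt(sum((clamped - pts[nrow(pts), ])^2))
    if (moved > 1e-9) {
      pts <- rbind(pts, clamped)
      len <- len + moved
    }
    if (any(clamped != nxt)) break  # hit the rhizotron wall
  }
  rownames(pts) <- NULL
  arcs <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  L <- arcs[length(arcs)]
  d <- if (L > 0) d0 * (1 - taper * arcs / L) else d0
  cbind(x = pts[, 1], y = pts[, 2], diameter = d)
}

# parent direction angle (from vertical) at an arc position, by secant
.tangentAngleAt <- function(polyline, arc, h = 0.5) {
  p1 <- pointAtArc(polyline, arc - h)
  p2 <- pointAtArc(polyline, arc + h)
  v <- p2 - p1
  if (sum(v^2) == 0) return(0)
  atan2(v[1], v[2])
}

#' Generate a synthetic maize-like root system
#'
#' Deterministic for a fixed seed. Random draws consume a single stream in
#' a fixed order: (1) seminal and adventitious axis counts; (2) for each
#' first-order axis in creation order (primary, seminals, adventitious) its
#' basal position jitter, initial heading, target length, diameter jitter
#' and per-step heading noise; (3) immediately after each root is grown,
#' its lateral count, insertion positions, and then each lateral
#' recursively (depth-first, in order of insertion). The caller's RNG
#' state is left untouched.
#'
#' @param params an [architectureParams()] list.
#' @param seed integer seed.
#' @param label plant label (defaults to a seed-derived tag).
#' @return a [RootSystem] that passes [validateSystem()], with all
#'   coordinates inside the rhizotron extent.
#' @export
generateRootSystem <- function(params = architectureParams(), seed = 1L,
                               label = sprintf("synthetic_seed%d", seed)) {
  if (!inherits(params, "ArchitectureParams"))
    stop("params must come from architectureParams()")
  .withSeed(seed, {
    ext <- params$extent
    roots <- list()

    addLaterals <- function(parentId, parentPl, parentOrder) {
      if (parentOrder >= params$maxOrder) return()
      L <- polylineLength(parentPl)
      zone <- L - params$apicalZone[parentOrder]
      if (zone <= 0) return()
      n <- stats::rpois(1, params$lateralDensity[parentOrder] * zone)
      if (n == 0) return()
      pos <- sort(stats::runif(n, 0, zone))
      for (j in seq_len(n)) {
        childOrder <- parentOrder + 1L
        side <- sample(c(-1, 1), 1)
        offset <- stats::runif(1, params$branchAngle[1],
                               params$branchAngle[2]) * pi / 180
        theta0 <- .tangentAngleAt(parentPl, pos[j]) + side * offset
        rng <- params$lateralLengthRange[[childOrder - 1L]]
        target <- stats::runif(1, rng[1], rng[2])
        d0 <- params$baseDiameter[childOrder] * stats::runif(1, 0.9, 1.1)
        start <- pointAtArc(parentPl, pos[j])
        pl <- .growPolyline(start, theta0,
                            params$gravitropism[childOrder],
                            params$headingNoiseSd[childOrder],
                            target, params$stepLength, ext, d0, params$taper)
        id <- sprintf("%s_%02d", parentId, j)
        roots[[id]] <<- Root(id, pl, order = childOrder,
                             parentId = parentId, insertion = pos[j])
        addLaterals(id, pl, childOrder)
      }
    }

    nSem <- sample(params$seminalRange[1]:params$seminalRange[2], 1)
    nAdv <- sample(params$adventitiousRange[1]:params$adventitiousRange[2], 1)
    kinds <- c(rep("primary", params$nPrimary), rep("seminal", nSem),
               rep("adventitious", nAdv))
    for (a in seq_along(kinds)) {
      x0 <- ext[1] / 2 + stats::runif(1, -1.5, 1.5)
      theta0 <- switch(kinds[a],
        primary = stats::rnorm(1, 0, 5 * pi / 180),
        seminal = (if (a %% 2 == 0) 1 else -1) *
          stats::runif(1, 15, 40) * pi / 180,
        adventitious = (if (a %% 2 == 0) 1 else -1) *
          stats::runif(1, 35, 65) * pi / 180)
      frac <- stats::runif(1, params$axisLengthFrac[1],
                           params$axisLengthFrac[2])
      mult <- switch(kinds[a], primary = 1, seminal = 0.85,
                     adventitious = 0.7)
      d0 <- params$baseDiameter[1] * stats::runif(1, 0.9, 1.1)
      pl <- .growPolyline(c(x0, 0), theta0, params$gravitropism[1],
                          params$headingNoiseSd[1],
                          frac * mult * ext[2], params$stepLength, ext,
                          d0, params$taper)
      id <- sprintf("ax%d", a)
      roots[[id]] <- Root(id, pl, order = 1L)
      addLaterals(id, pl, 1L)
    }
    sys <- RootSystem(roots, label = label, extent = ext)
    stopifnot(nrow(validateSystem(sys)) == 0L)
    sys
  })
}

#' Split a root system into partial tracings
#'
#' One [PartialTracing] per first-order axis, each carrying the axis and
#' its whole lateral subtree, with offsets (0, 0). This emulates the
#' physical dissociation of the root system into fragments before
#' scanning; [mergeTracings()] over the result reproduces the original
#' system.
#'
#' @param system a [RootSystem].
#' @return list of [PartialTracing] (empty for an empty system).
#' @export
splitSystem <- function(system) {
  bases <- sort(names(system@roots)[vapply(system@roots, function(r)
    is.na(r@parentId) & r@order == 1L, logical(1))])
  lapply(bases, function(b) {
    ids <- c(b, descendantIds(system, b))
    PartialTracing(RootSystem(system@roots[ids],
                              label = paste0(system@label, ":", b),
                              extent = system@extent),
                   offset = c(0, 0))
  })
}

#' Render a root system as a binary mask
#'
#' Rasterizes every segment as a stroked line whose width is the local mean
#' diameter, with a floor of one pixel, over the rhizotron extent. This is
#' the synthetic analog of an ex-situ binary root scan; its foreground area
#' is comparable to the vector projected area (length x diameter).
#'
#' @param system a [RootSystem].
#' @param pixelsPerCm raster resolution, >= 5 so that lateral strokes span
#'   at least a pixel without gross inflation.
#' @return object of class `rootMask`: list with `mask` (logical matrix,
#'   rows = y), `pixelsPerCm` and `extent`.
#' @export
renderMask <- function(system, pixelsPerCm) {
  pixelsPerCm <- as.integer(pixelsPerCm)
  if (pixelsPerCm < 5L) stop("pixelsPerCm must be >= 5")
  h <- 1 / pixelsPerCm
  nc <- as.integer(round(system@extent[1] * pixelsPerCm))
  nr <- as.integer(round(system@extent[2] * pixelsPerCm))
  mask <- matrix(FALSE, nr, nc)
  cx <- (seq_len(nc) - 0.5) * h
  cy <- (seq_len(nr) - 0.5) * h
  for (r in system@roots) {
    pl <- r@polyline
    n <- nrow(pl)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      w <- max((pl[i, "diameter"] + pl[i + 1L, "diameter"]) / 2, h)
      half <- w / 2
      xr <- range(pl[i:(i + 1L), "x"]); yr <- range(pl[i:(i + 1L), "y"])
      jc <- which(cx >= xr[1] - half - h & cx <= xr[2] + half + h)
      ir <- which(cy >= yr[1] - half - h & cy <= yr[2] + half + h)
      if (!length(jc) || !length(ir)) next
      px <- rep(cx[jc], each = length(ir))
      py <- rep(cy[ir], times = length(jc))
      d <- .pointsToSegment(px, py, pl[i, "x"], pl[i, "y"],
                            pl[i + 1L, "x"], pl[i + 1L, "y"])
      hit <- matrix(d <= half, length(ir), length(jc))
      mask[ir, jc] <- mask[ir, jc] | hit
    }
  }
  structure(list(mask = mask, pixelsPerCm = pixelsPerCm,
                 extent = system@extent), class = "rootMask")
}

#' Foreground area of a rendered mask
#' @param mask a `rootMask` from [renderMask()].
#' @return area in cm^2.
#' @export
maskArea <- function(mask) sum(mask$mask) / mask$pixelsPerCm^2

#' Write a mask as a PNG image
#' @param mask a `rootMask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(1 - mask$mask * 1, path)  # roots black on white
  invisible(path)
}

#' @export
print.rootMask <- function(x, ...) {
  cat(sprintf("rootMask %d x %d px @ %d px/cm, area %.3f cm^2\n",
              nrow(x$mask), ncol(x$mask), x$pixelsPerCm, maskArea(x)))
  invisible(x)
}

# ---- water depletion maps --------------------------------------------------

#' Water-depletion model parameters
#'
#' The synthetic soil water content at a pixel with distance `d` (cm) to
#' the nearest root at time `t` (hours) is
#' `W(d, t) = clip(W0(t) - A(t) * exp(-d / ell) + noise, 0, 1)`:
#' a bulk content `W0(t)` declining linearly with cumulative daytime hours
#' (transpiration stops at night), minus an exponential draw-down around
#' roots of amplitude `A(t)` (nondecreasing during the day, reduced by
#' `nightRecovery` at night to mimic nocturnal redistribution of soil
#' water) and length scale `ell`.
#'
#' @param W0start bulk water-content index at t = 0.
#' @param dayDecline bulk decline per daytime hour.
#' @param A0,Amax initial and final depletion amplitudes; the amplitude
#'   ramps linearly with cumulative daytime hours over `rampDayHours`.
#' @param rampDayHours daytime hours over which the amplitude ramps.
#' @param ell depletion length scale (cm).
#' @param noiseSd gaussian measurement noise sd.
#' @param timestamps observation times (hours; default every 4 h over 3
#'   days).
#' @param dayStart,dayEnd hours-of-day delimiting daytime.
#' @param nightRecovery fractional amplitude reduction at night.
#' @return a named list of class `WaterModelParams`.
#' @export
waterModelParams <- function(W0start = 0.75, dayDecline = 0.0035,
                             A0 = 0.15, Amax = 0.4, rampDayHours = 24,
                             ell = 2, noiseSd = 0.01,
                             timestamps = seq(0, 72, by = 4),
                             dayStart = 6, dayEnd = 18,
                             nightRecovery = 0.3) {
  p <- list(W0start = W0start, dayDecline = dayDecline, A0 = A0,
            Amax = Amax, rampDayHours = rampDayHours, ell = ell,
            noiseSd = noiseSd, timestamps = timestamps,
            dayStart = dayStart, dayEnd = dayEnd,
            nightRecovery = nightRecovery)
  stopifnot(p$ell > 0, p$noiseSd >= 0, p$dayEnd > p$dayStart,
            p$nightRecovery >= 0, p$nightRecovery <= 1,
            all(diff(p$timestamps) > 0))
  class(p) <- "WaterModelParams"
  p
}

# cumulative daytime hours in [0, t]
.dayHours <- function(t, dayStart, dayEnd) {
  span <- dayEnd - dayStart
  full <- floor(t / 24) * span
  rem <- t %% 24
  full + min(max(rem - dayStart, 0), span)
}

#' Deterministic part of the water model
#'
#' Bulk content, depletion amplitude and day/night flag at given times,
#' noise-free — the ground truth the generated series is built from.
#'
#' @param t numeric vector of times (hours).
#' @param params a [waterModelParams()] list.
#' @return data.frame with columns `time_h`, `W0`, `A`, `night`.
#' @export
waterModelCurves <- function(t, params = waterModelParams()) {
  D <- vapply(t, .dayHours, numeric(1), params$dayStart, params$dayEnd)
  hod <- t %% 24
  night <- hod < params$dayStart | hod >= params$dayEnd
  A <- params$A0 + (params$Amax - params$A0) *
    pmin(1, D / params$rampDayHours)
  A[night] <- A[night] * (1 - params$nightRecovery)
  data.frame(time_h = t, W0 = params$W0start - params$dayDecline * D,
             A = A, night = night)
}

#' Generate a synthetic soil water-content series
#'
#' Builds the time-invariant [distanceMap()] of the system on the given
#' geometry, then applies the depletion model of [waterModelParams()] at
#' every timestamp, adding gaussian noise and clipping to [0, 1].
#' Deterministic for a fixed seed (one noise matrix drawn per timestamp,
#' in time order).
#'
#' @param system a [RootSystem].
#' @param geometry a [SoilGrid], [DistanceMap] or
#'   `list(nrow, ncol, origin, pixelSize)` covering the system extent.
#' @param params a [waterModelParams()] list.
#' @param seed integer seed for the noise stream.
#' @return list of [SoilGrid], one per timestamp, in time order.
#' @export
generateWaterSeries <- function(system, geometry,
                                params = waterModelParams(), seed = 1L) {
  if (!inherits(params, "WaterModelParams"))
    stop("params must come from waterModelParams()")
  dmap <- distanceMap(system, geometry)
  curves <- waterModelCurves(params$timestamps, params)
  .withSeed(seed, {
    lapply(seq_len(nrow(curves)), function(i) {
      w <- curves$W0[i] - curves$A[i] * exp(-dmap@distance / params$ell)
      if (params$noiseSd > 0)
        w <- w + stats::rnorm(length(w), 0, params$noiseSd)
      SoilGrid(pmin(pmax(w, 0), 1), origin = dmap@origin,
               pixelSize = dmap@pixelSize,
               timestamp = curves$time_h[i])
    })
  })
}
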
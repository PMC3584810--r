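# Architectural trait suite: per-root morphology, distal cumulative
# measures, depth profiles by order, diameter statistics with compact
# letter display, surface proportions, orientation profiles and Fitter
# topological indices.

#' Per-root trait table
#'
#' One row per root: order, parent, total length (cm), lateral surface
#' (cm^2), volume (cm^3), projected area (cm^2, length x mean diameter — the
#' quantity a binary scan mask measures), length-weighted mean diameter
#' (cm), insertion position on the parent (cm) and tip depth (cm).
#'
#' @param system a [RootSystem].
#' @return data.frame with columns `id`, `order`, `parentId`, `length_cm`,
#'   `surface_cm2`, `volume_cm3`, `projected_area_cm2`, `mean_diameter_cm`,
#'   `insertion_cm`, `tip_depth_cm`.
#' @export
rootTraits <- function(system) {
  rows <- lapply(system@roots, function(r) {
    m <- .polylineMeasures(r@polyline)
    L <- sum(m[, "length"])
    meanD <- if (L > 0) {
      n <- nrow(r@polyline)
      dmid <- (r@polyline[-n, "diameter"] + r@polyline[-1, "diameter"]) / 2
      sum(dmid * m[, "length"]) / L
    } else r@polyline[1, "diameter"]
    data.frame(id = r@id, order = r@order, parentId = r@parentId,
               length_cm = L,
               surface_cm2 = sum(m[, "surface"]),
               volume_cm3 = sum(m[, "volume"]),
               projected_area_cm2 = sum(m[, "projected"]),
               mean_diameter_cm = meanD,
               insertion_cm = r@insertion,
               tip_depth_cm = r@polyline[nrow(r@polyline), "y"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(id = character(0), order = integer(0),
                      parentId = character(0), length_cm = numeric(0),
                      surface_cm2 = numeric(0), volume_cm3 = numeric(0),
                      projected_area_cm2 = numeric(0),
                      mean_diameter_cm = numeric(0),
                      insertion_cm = numeric(0), tip_depth_cm = numeric(0),
                      stringsAsFactors = FALSE)
  out
}

# total measure (length/surface/volume) of a root plus all its descendants
.subtreeTotal <- function(system, id, measure) {
  own <- sum(.polylineMeasures(system@roots[[id]]@polyline)[, measure])
  for (cid in childIds(system, id))
    own <- own + .subtreeTotal(system, cid, measure)
  own
}

#' Cumulative measure distal to a position on a root
#'
#' Sums the chosen measure over (a) the part of the root tipward of the
#' arc-length `position` and (b) the entire subtrees of all laterals whose
#' insertion position is at or beyond `position`. Evaluated at the base
#' (`position = 0`) of a first-order axis this is the whole-tree total; at
#' the tip it is 0. Under the assumption that water moving through a
#' root's cross-section at a point must supply everything distal of it, the
#' distal cumulative volume profiles axial flow demand along an axis.
#'
#' @param system a [RootSystem].
#' @param rootId id of the root carrying the query position.
#' @param position arc length from the root base, cm, in `[0, root length]`.
#' @param measure one of `"length"`, `"surface"`, `"volume"`.
#' @return numeric(1), in cm / cm^2 / cm^3.
#' @export
distalCumulative <- function(system, rootId, position,
                             measure = c("surface", "length", "volume")) {
  measure <- match.arg(measure)
  if (!rootId %in% names(system@roots))
    stop("unknown root id: ", rootId)
  r <- system@roots[[rootId]]
  pl <- r@polyline
  arcs <- arcPositions(pl)
  L <- arcs[length(arcs)]
  if (position < -1e-12 || position > L + 1e-12)
    stop("position ", position, " outside [0, ", L, "]")
  position <- min(max(position, 0), L)

  total <- 0
  m <- .polylineMeasures(pl)
  n <- nrow(pl)
  for (i in seq_len(max(n - 1L, 0L))) {
    a0 <- arcs[i]; a1 <- arcs[i + 1L]
    if (a1 <= position) next
    if (a0 >= position) {
      total <- total + m[i, measure]
    } else if (a1 > a0) {
      # split the segment at the query position; diameter is linear in arc,
      # so the frustum measures subdivide exactly
      t <- (position - a0) / (a1 - a0)
      dsplit <- pl[i, "diameter"] + t * (pl[i + 1L, "diameter"] - pl[i, "diameter"])
      seg <- segmentMeasures(
        c(0, 0, dsplit), c((1 - t) * (a1 - a0), 0, pl[i + 1L, "diameter"]))
      total <- total + seg[[measure]]
    }
  }
  for (cid in childIds(system, rootId)) {
    if (system@roots[[cid]]@insertion >= position)
      total <- total + .subtreeTotal(system, cid, measure)
  }
  unname(total)
}

#' Root length depth profile by order
#'
#' Apportions every segment's length to horizontal depth slabs
#' `[k*binSize, (k+1)*binSize)` by exact clipping, so per-order bin sums
#' equal per-order totals.
#'
#' @param system a [RootSystem].
#' @param binSize slab thickness in cm (default 1).
#' @return data.frame with columns `order`, `bin_lo`, `bin_hi`,
#'   `length_cm`, covering every slab intersected by at least one segment.
#' @export
depthProfile <- function(system, binSize = 1) {
  if (binSize <= 0) stop("binSize must be > 0")
  acc <- new.env(parent = emptyenv())
  put <- function(ord, bin, len) {
    key <- paste(ord, bin)
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + len
  }
  for (r in system@roots) {
    pl <- r@polyline
    n <- nrow(pl)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      y1 <- pl[i, "y"]; y2 <- pl[i + 1L, "y"]
      L <- sqrt((pl[i + 1L, "x"] - pl[i, "x"])^2 + (y2 - y1)^2)
      if (L == 0) next
      if (y1 == y2) {
        put(r@order, floor(y1 / binSize), L)
      } else {
        ylo <- min(y1, y2); yhi <- max(y1, y2)
        for (k in floor(ylo / binSize):floor((yhi) / binSize)) {
          ov <- min(yhi, (k + 1) * binSize) - max(ylo, k * binSize)
          if (ov > 0) put(r@order, k, L * ov / (yhi - ylo))
        }
      }
    }
  }
  keys <- ls(acc)
  if (!length(keys))
    return(data.frame(order = integer(0), bin_lo = numeric(0),
                      bin_hi = numeric(0), length_cm = numeric(0)))
  parts <- do.call(rbind, strsplit(keys, " "))
  out <- data.frame(order = as.integer(parts[, 1]),
                    bin_lo = as.numeric(parts[, 2]) * binSize,
                    length_cm = vapply(keys, function(k) acc[[k]], numeric(1)))
  out$bin_hi <- out$bin_lo + binSize
  out <- out[order(out$order, out$bin_lo), c("order", "bin_lo", "bin_hi",
                                             "length_cm")]
  rownames(out) <- NULL
  out
}

# insert-and-absorb compact letter display over a non-rejection matrix.
# ns[i, j] TRUE when groups i and j are NOT significantly different.
.compactLetters <- function(ns) {
  g <- nrow(ns)
  cols <- list(seq_len(g))  # start with one column holding all groups
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    if (ns[i, j]) next
    for (ci in seq_along(cols)) {
      if (i %in% cols[[ci]] && j %in% cols[[ci]]) {
        a <- setdiff(cols[[ci]], i)
        b <- setdiff(cols[[ci]], j)
        cols[[ci]] <- a
        cols[[length(cols) + 1L]] <- b
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(cols))
    for (ci in seq_along(cols)) for (cj in seq_along(cols)) {
      if (ci != cj && keep[ci] && keep[cj] &&
          all(cols[[ci]] %in% cols[[cj]]))
        keep[ci] <- FALSE
    }
    cols <- cols[keep]
  }
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  letters_out <- rep("", g)
  for (ci in seq_along(cols))
    for (gi in cols[[ci]])
      letters_out[gi] <- paste0(letters_out[gi], letters[ci])
  letters_out
}

#' Per-order diameter statistics with compact letter display
#'
#' Each root is summarized by its length-weighted mean diameter; orders are
#' then compared with pairwise Welch (unequal-variance) t-tests at the given
#' significance level, and letters are assigned by the insert-and-absorb
#' compact letter display: orders sharing a letter are not significantly
#' different. Orders with fewer than 2 roots are reported without a letter.
#'
#' @param system a [RootSystem].
#' @param alpha significance level (default 0.01).
#' @return data.frame with columns `order`, `n`, `mean_diameter_cm`,
#'   `sd_diameter_cm`, `letter`.
#' @export
diameterStats <- function(system, alpha = 0.01) {
  tt <- rootTraits(system)
  if (!nrow(tt)) stop("empty system")
  samples <- split(tt$mean_diameter_cm, tt$order)
  ords <- as.integer(names(samples))
  n <- lengths(samples)
  testable <- which(n >= 2L)
  letter <- rep(NA_character_, length(ords))
  if (length(testable) == 1L) {
    letter[testable] <- "a"
  } else if (length(testable) > 1L) {
    k <- length(testable)
    ns <- matrix(TRUE, k, k)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      xi <- samples[[testable[i]]]; xj <- samples[[testable[j]]]
      p <- if (stats::sd(xi) == 0 && stats::sd(xj) == 0)
        as.numeric(mean(xi) == mean(xj))  # degenerate: identical -> 1, else 0
      else stats::t.test(xi, xj, var.equal = FALSE)$p.value
      ns[i, j] <- ns[j, i] <- p >= alpha
    }
    letter[testable] <- .compactLetters(ns)
  }
  data.frame(order = ords, n = as.integer(n),
             mean_diameter_cm = vapply(samples, mean, numeric(1)),
             sd_diameter_cm = vapply(samples, stats::sd, numeric(1)),
             letter = letter, row.names = NULL, stringsAsFactors = FALSE)
}

#' Surface proportion of each root order
#'
#' @param system a [RootSystem] with positive total surface.
#' @return named numeric vector (names `"1"`, `"2"`, ...) of fractions in
#'   [0, 1] summing to 1.
#' @export
surfaceProportions <- function(system) {
  tt <- rootTraits(system)
  tot <- sum(tt$surface_cm2)
  if (!nrow(tt) || tot <= 0)
    stop("surface proportions undefined: total surface is zero")
  s <- tapply(tt$surface_cm2, tt$order, sum)
  out <- as.numeric(s) / tot
  names(out) <- names(s)
  out
}

#' Orientation of a root along its axis
#'
#' At each polyline node's arc-length position, the local growth direction
#' is taken as the secant over a centered arc-length window (clamped at the
#' root ends) and reported as the unsigned angle from the vertical-down
#' direction, in degrees: 0 for a plumb root, 90 for horizontal growth.
#'
#' @param root a [Root] with positive length.
#' @param window secant window in cm (default 1).
#' @return data.frame with columns `arc_cm`, `angle_deg` (in [0, 180]).
#' @export
orientationProfile <- function(root, window = 1) {
  if (window <= 0) stop("window must be > 0")
  pl <- root@polyline
  arcs <- arcPositions(pl)
  L <- arcs[length(arcs)]
  if (L <= 0) stop("zero-length root")
  ang <- vapply(arcs, function(s) {
    p1 <- pointAtArc(pl, s - window / 2)
    p2 <- pointAtArc(pl, s + window / 2)
    v <- p2 - p1
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(NA_real_)
    acos(pmin(pmax(v[2] / nv, -1), 1)) * 180 / pi
  }, numeric(1))
  data.frame(arc_cm = arcs, angle_deg = ang)
}

#' Fitter topological indices
#'
#' Treats each first-order axis and its laterals as a branching tree of
#' links (the internodes between branching points and tips): magnitude is
#' the number of tips, altitude the number of links on the longest
#' base-to-tip path, and the total exterior path length the sum over all
#' tips of the link count from the base. Laterals inserted at exactly the
#' same arc position share a branching point.
#'
#' @param system a [RootSystem].
#' @return data.frame with one row per tree: `treeId` (the order-1 root),
#'   `magnitude`, `altitude`, `exterior_path_length`.
#' @export
fitterIndices <- function(system) {
  bases <- sort(names(system@roots)[vapply(system@roots, function(r)
    is.na(r@parentId), logical(1))])
  rows <- lapply(bases, function(b) {
    tipDepths <- numeric(0)
    recurse <- function(id, baseDepth) {
      kids <- childIds(system, id)
      pos <- vapply(kids, function(k) system@roots[[k]]@insertion, numeric(1))
      o <- order(pos, kids)
      kids <- kids[o]; pos <- pos[o]
      upos <- unique(pos)
      for (i in seq_along(kids))
        recurse(kids[i], baseDepth + match(pos[i], upos))
      tipDepths <<- c(tipDepths, baseDepth + length(upos) + 1)
    }
    recurse(b, 0)
    data.frame(treeId = b, magnitude = length(tipDepths),
               altitude = as.integer(max(tipDepths)),
               exterior_path_length = as.integer(sum(tipDepths)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(treeId = character(0), magnitude = integer(0),
                      altitude = integer(0),
                      exterior_path_length = integer(0),
                      stringsAsFactors = FALSE)
  out
}

#' Whole-system totals
#'
#' @param system a [RootSystem].
#' @return numeric(1): total length (cm) / surface (cm^2).
#' @name totals
#' @export
totalLength <- function(system) sum(rootTraits(system)$length_cm)

#' @rdname totals
#' @export
totalSurface <- function(system) sum(rootTraits(system)$surface_cm2)
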
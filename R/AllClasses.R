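#' @import methods
NULL

#' Root: a single vectorized root
#'
#' A root is an ordered polyline of nodes, each node carrying an x coordinate
#' (cm, rightward), a y coordinate (cm, positive downward = depth) and a
#' diameter (cm). A root knows its branching order (1 = axis emitted at the
#' plant base, 2 and 3 = successive laterals), the id of its parent root (or
#' `NA` for first-order axes and detached laterals) and, when attached, the
#' arc-length position on the parent at which it inserts.
#'
#' @slot id character(1), unique within a [RootSystem].
#' @slot order integer(1), branching order in 1..3.
#' @slot parentId character(1) or `NA`.
#' @slot insertion numeric(1), arc length (cm) on the parent polyline at the
#'   insertion point; `NA` iff `parentId` is `NA`.
#' @slot polyline numeric matrix with columns `x`, `y`, `diameter` and at
#'   least one row.
#'
#' @exportClass Root
setClass("Root", representation(
  id = "character",
  order = "integer",
  parentId = "character",
  insertion = "numeric",
  polyline = "matrix"
))

setValidity("Root", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "id must be a non-empty character(1)")
  if (length(object@order) != 1L || is.na(object@order) || object@order < 1L)
    msg <- c(msg, "order must be a positive integer")
  pl <- object@polyline
  if (!is.numeric(pl) || ncol(pl) != 3L || nrow(pl) < 1L)
    msg <- c(msg, "polyline must be a numeric matrix with >= 1 row and columns x, y, diameter")
  else {
    if (!identical(colnames(pl), c("x", "y", "diameter")))
      msg <- c(msg, "polyline columns must be named x, y, diameter")
    if (any(!is.finite(pl[, 1:2])))
      msg <- c(msg, "coordinates must be finite")
    if (any(!is.finite(pl[, 3]) | pl[, 3] < 0))
      msg <- c(msg, "diameters must be finite and >= 0")
  }
  if (length(object@parentId) != 1L || length(object@insertion) != 1L)
    msg <- c(msg, "parentId and insertion must have length 1")
  else if (is.na(object@parentId) && !is.na(object@insertion))
    msg <- c(msg, "insertion must be NA when parentId is NA")
  if (length(msg)) msg else TRUE
})

#' RootSystem: a collection of roots in a common rhizotron frame
#'
#' @slot roots list of [Root] objects, named by root id.
#' @slot label character(1), free-text plant label.
#' @slot extent numeric(2), rhizotron width and height in cm (default 50 x 50).
#' @slot metadata list of auxiliary information (e.g. the merge report left by
#'   [mergeTracings()]).
#'
#' Validity enforces structural sanity only: unique ids, every non-`NA`
#' `parentId` resolving to a root in the system, and no parent self-reference.
#' Scientific consistency (orders, insertion ranges, acyclicity) is checked by
#' [validateSystem()], which reports violations instead of refusing to hold
#' them: the split-and-combine workflow legitimately carries orphan laterals
#' until they are attached.
#'
#' @exportClass RootSystem
setClass("RootSystem", representation(
  roots = "list",
  label = "character",
  extent = "numeric",
  metadata = "list"
))

setValidity("RootSystem", function(object) {
  msg <- character()
  if (length(object@extent) != 2L || any(!is.finite(object@extent)) ||
      any(object@extent <= 0))
    msg <- c(msg, "extent must be two positive finite numbers (width, height cm)")
  if (!all(vapply(object@roots, is, logical(1), "Root")))
    msg <- c(msg, "roots must be a list of Root objects")
  else {
    ids <- unname(vapply(object@roots, function(r) r@id, character(1)))
    if (anyDuplicated(ids))
      msg <- c(msg, "root ids must be unique")
    if (length(ids) && !identical(names(object@roots), ids))
      msg <- c(msg, "roots list must be named by root id")
    par <- vapply(object@roots, function(r) r@parentId, character(1))
    bad <- !is.na(par) & !(par %in% ids)
    if (any(bad))
      msg <- c(msg, paste0("unresolved parent ids: ",
                           paste(unique(par[bad]), collapse = ", ")))
    if (any(!is.na(par) & par == ids))
      msg <- c(msg, "a root cannot be its own parent")
  }
  if (length(msg)) msg else TRUE
})

#' PartialTracing: one scanned fragment plus its registration offset
#'
#' In the split-and-combine procedure every root-system fragment is scanned
#' and traced separately; the acetate tracing registers all fragments in the
#' common rhizotron frame. A `PartialTracing` holds one fragment as a
#' [RootSystem] plus the (x, y) translation (cm) taking its local coordinates
#' into the common frame.
#'
#' @slot system a [RootSystem] fragment.
#' @slot offset numeric(2), translation in cm.
#'
#' @exportClass PartialTracing
setClass("PartialTracing", representation(
  system = "RootSystem",
  offset = "numeric"
))

setValidity("PartialTracing", function(object) {
  if (length(object@offset) != 2L || any(!is.finite(object@offset)))
    return("offset must be two finite numbers (cm)")
  TRUE
})

#' SoilGrid: a timestamped raster of soil water content
#'
#' Values are a unitless water-content index in [0, 1] on a regular grid of
#' square pixels. The grid is georeferenced in rhizotron coordinates by its
#' origin (top-left corner of pixel [1, 1], cm) and pixel size (cm); pixel
#' centers sit at `origin + (index - 0.5) * pixelSize`.
#'
#' @slot values numeric matrix (rows = y/depth, cols = x).
#' @slot origin numeric(2), (x, y) of the grid's top-left corner in cm.
#' @slot pixelSize numeric(1), side of a pixel in cm, > 0.
#' @slot timestamp numeric(1), hours since the start of the series.
#'
#' @exportClass SoilGrid
setClass("SoilGrid", representation(
  values = "matrix",
  origin = "numeric",
  pixelSize = "numeric",
  timestamp = "numeric"
))

setValidity("SoilGrid", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v) || nrow(v) < 1L || ncol(v) < 1L)
    msg <- c(msg, "values must be a non-empty numeric matrix")
  else if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    msg <- c(msg, "water-content values must be finite and in [0, 1]")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be two finite numbers (cm)")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number (cm)")
  if (length(object@timestamp) != 1L || !is.finite(object@timestamp))
    msg <- c(msg, "timestamp must be a single finite number (hours)")
  if (length(msg)) msg else TRUE
})

#' DistanceMap: per-pixel distance to the nearest root segment
#'
#' For every pixel center of a grid geometry, the minimum euclidean distance
#' (cm) to any root segment of a [RootSystem], together with the id and order
#' of the root owning the nearest segment. Ties between roots are broken by
#' the lexicographically smallest root id, so maps are reproducible.
#'
#' @slot distance numeric matrix of distances (cm), >= 0.
#' @slot nearestId character matrix of nearest root ids.
#' @slot nearestOrder integer matrix of nearest root orders.
#' @slot origin numeric(2), grid origin (cm).
#' @slot pixelSize numeric(1), pixel size (cm).
#'
#' @exportClass DistanceMap
setClass("DistanceMap", representation(
  distance = "matrix",
  nearestId = "matrix",
  nearestOrder = "matrix",
  origin = "numeric",
  pixelSize = "numeric"
))

setValidity("DistanceMap", function(object) {
  msg <- character()
  d <- object@distance
  if (any(!is.finite(d)) || any(d < 0))
    msg <- c(msg, "distances must be finite and >= 0")
  if (!identical(dim(d), dim(object@nearestId)) ||
      !identical(dim(d), dim(object@nearestOrder)))
    msg <- c(msg, "distance, nearestId and nearestOrder must share dimensions")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

# ---- constructors ----------------------------------------------------------

#' Create a Root
#'
#' @param id root id (unique within its system).
#' @param polyline numeric matrix or data.frame with columns `x`, `y`,
#'   `diameter` (cm), one row per node, base first.
#' @param order branching order (1..3).
#' @param parentId id of the parent root, or `NA` for a first-order axis or a
#'   detached lateral.
#' @param insertion arc-length position (cm) of the insertion point on the
#'   parent; `NA` iff `parentId` is `NA`.
#' @return a [Root] object.
#' @examples
#' Root("ax1", cbind(x = c(25, 25), y = c(0, 10), diameter = 0.4))
#' @export
Root <- function(id, polyline, order = 1L, parentId = NA_character_,
                 insertion = NA_real_) {
  pl <- as.matrix(polyline)
  if (is.null(colnames(pl))) colnames(pl) <- c("x", "y", "diameter")
  pl <- pl[, c("x", "y", "diameter"), drop = FALSE]
  storage.mode(pl) <- "double"
  new("Root", id = as.character(id), order = as.integer(order),
      parentId = as.character(parentId), insertion = as.numeric(insertion),
      polyline = pl)
}

#' Create a RootSystem
#'
#' @param roots list of [Root] objects.
#' @param label plant label.
#' @param extent rhizotron width and height in cm.
#' @param metadata list of auxiliary information.
#' @return a [RootSystem].
#' @examples
#' ax <- Root("ax1", cbind(x = c(25, 25), y = c(0, 10), diameter = 0.4))
#' RootSystem(list(ax), label = "demo")
#' @export
RootSystem <- function(roots = list(), label = "", extent = c(50, 50),
                       metadata = list()) {
  names(roots) <- vapply(roots, function(r) r@id, character(1))
  new("RootSystem", roots = roots, label = as.character(label),
      extent = as.numeric(extent), metadata = metadata)
}

#' Create a PartialTracing
#'
#' @param system a [RootSystem] fragment.
#' @param offset numeric(2): translation (cm) into the common frame.
#' @return a [PartialTracing].
#' @export
PartialTracing <- function(system, offset = c(0, 0)) {
  new("PartialTracing", system = system, offset = as.numeric(offset))
}

#' Create a SoilGrid
#'
#' @param values numeric matrix of water-content indices in [0, 1].
#' @param origin (x, y) of the top-left grid corner, cm.
#' @param pixelSize pixel side, cm.
#' @param timestamp hours since the start of the series.
#' @return a [SoilGrid].
#' @examples
#' SoilGrid(matrix(0.7, 10, 10), pixelSize = 1, timestamp = 0)
#' @export
SoilGrid <- function(values, origin = c(0, 0), pixelSize = 1, timestamp = 0) {
  new("SoilGrid", values = as.matrix(values), origin = as.numeric(origin),
      pixelSize = as.numeric(pixelSize), timestamp = as.numeric(timestamp))
}

# ---- show methods ----------------------------------------------------------

setMethod("show", "Root", function(object) {
  cat(sprintf("Root '%s' (order %d): %d node(s), length %.3f cm%s\n",
              object@id, object@order, nrow(object@polyline),
              polylineLength(object@polyline),
              if (is.na(object@parentId)) ""
              else sprintf(", on '%s' at %.3f cm", object@parentId,
                           object@insertion)))
})

setMethod("show", "RootSystem", function(object) {
  ords <- vapply(object@roots, function(r) r@order, integer(1))
  cat(sprintf("RootSystem '%s': %d root(s) in a %g x %g cm rhizotron\n",
              object@label, length(object@roots),
              object@extent[1], object@extent[2]))
  if (length(ords))
    cat("  per order:",
        paste(sprintf("%d@order%d", tabulate(ords, 3L), 1:3), collapse = ", "),
        "\n")
})

setMethod("show", "PartialTracing", function(object) {
  cat(sprintf("PartialTracing: %d root(s), offset (%g, %g) cm\n",
              length(object@system@roots), object@offset[1], object@offset[2]))
})

setMethod("show", "SoilGrid", function(object) {
  cat(sprintf(
    "SoilGrid %d x %d @ %g cm/px, origin (%g, %g) cm, t = %g h, mean %.4f\n",
    nrow(object@values), ncol(object@values), object@pixelSize,
    object@origin[1], object@origin[2], object@timestamp,
    mean(object@values)))
})

setMethod("show", "DistanceMap", function(object) {
  cat(sprintf("DistanceMap %d x %d @ %g cm/px, distances %.3f..%.3f cm\n",
              nrow(object@distance), ncol(object@distance), object@pixelSize,
              min(object@distance), max(object@distance)))
})

# ---- accessors -------------------------------------------------------------

#' Root and system accessors
#'
#' Small accessor family avoiding direct slot access: `rootIds` returns the
#' ids of all roots, `nRoots` their count, `getRoot` one [Root] by id,
#' `rootOrders` the named integer vector of orders, and `rhizotronExtent`
#' the (width, height) of the frame in cm.
#'
#' @param x a [RootSystem].
#' @param id a root id.
#' @name accessors
#' @export
rootIds <- function(x) names(x@roots)

#' @rdname accessors
#' @export
nRoots <- function(x) length(x@roots)

#' @rdname accessors
#' @export
getRoot <- function(x, id) {
  if (!id %in% names(x@roots)) stop("unknown root id: ", id)
  x@roots[[id]]
}

#' @rdname accessors
#' @export
rootOrders <- function(x) vapply(x@roots, function(r) r@order, integer(1))

#' @rdname accessors
#' @export
rhizotronExtent <- function(x) x@extent

#' SoilGrid accessors
#'
#' @param x a [SoilGrid] or [DistanceMap].
#' @name grid-accessors
#' @export
gridValues <- function(x) x@values

#' @rdname grid-accessors
#' @export
gridOrigin <- function(x) x@origin

#' @rdname grid-accessors
#' @export
pixelSize <- function(x) x@pixelSize

#' @rdname grid-accessors
#' @export
gridTimestamp <- function(x) x@timestamp

#' Distance map accessors
#'
#' @param x a [DistanceMap].
#' @name dmap-accessors
#' @export
distanceValues <- function(x) x@distance

#' @rdname dmap-accessors
#' @export
nearestRootId <- function(x) x@nearestId

#' @rdname dmap-accessors
#' @export
nearestRootOrder <- function(x) x@nearestOrder
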
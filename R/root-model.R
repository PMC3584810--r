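# Root-system model operations: validation, topology edits and the
# split-and-combine merge of registered partial tracings.

# children of a root, as ids (named lookup avoids repeated vapply scans)
.parentVector <- function(system) {
  vapply(system@roots, function(r) r@parentId, character(1))
}

#' Ids of the direct children of a root
#' @param system a [RootSystem].
#' @param id a root id.
#' @return character vector of child ids.
#' @export
childIds <- function(system, id) {
  par <- .parentVector(system)
  names(par)[!is.na(par) & par == id]
}

#' Ids of all descendants of a root (children, grandchildren, ...)
#' @inheritParams childIds
#' @export
descendantIds <- function(system, id) {
  out <- character(0)
  frontier <- childIds(system, id)
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(lapply(frontier, childIds, system = system),
                       use.names = FALSE)
  }
  out
}

#' Validate a root system
#'
#' Checks the scientific consistency rules a finished tracing must obey and
#' returns a report of every violation found: parent cycles, dangling parent
#' ids, order inconsistencies (`order == 1` iff no parent, otherwise
#' `parent order + 1`, never above 3), negative diameters and insertion
#' positions outside `[0, parent length]`. An empty report (zero rows) means
#' the system is valid. Reporting rather than erroring lets the merge
#' workflow hold intermediate states (e.g. orphan laterals awaiting a
#' parent).
#'
#' @param system a [RootSystem].
#' @return data.frame with columns `rootId`, `type`, `message`; zero rows iff
#'   valid.
#' @export
validateSystem <- function(system) {
  rep <- list()
  add <- function(id, type, msg)
    rep[[length(rep) + 1L]] <<- data.frame(rootId = id, type = type,
                                           message = msg,
                                           stringsAsFactors = FALSE)
  roots <- system@roots
  ids <- names(roots)
  par <- .parentVector(system)

  for (id in ids) {
    r <- roots[[id]]
    if (any(r@polyline[, "diameter"] < 0))
      add(id, "diameter", "negative diameter")
    p <- r@parentId
    if (is.na(p)) {
      if (r@order != 1L)
        add(id, "order", sprintf("order %d root has no parent (orphan)",
                                 r@order))
    } else if (!p %in% ids) {
      add(id, "parent", sprintf("dangling parent id '%s'", p))
    } else {
      if (r@order != roots[[p]]@order + 1L)
        add(id, "order",
            sprintf("order %d under an order-%d parent", r@order,
                    roots[[p]]@order))
      pl <- polylineLength(roots[[p]]@polyline)
      if (is.na(r@insertion) || r@insertion < 0 || r@insertion > pl + 1e-9)
        add(id, "insertion",
            sprintf("insertion %.4g outside [0, %.4g]", r@insertion, pl))
    }
    if (r@order > 3L)
      add(id, "order", sprintf("order %d exceeds the maximum of 3", r@order))
  }

  # cycle detection by following parent pointers
  state <- setNames(integer(length(ids)), ids)  # 0 new, 1 active, 2 done
  for (id in ids) {
    if (state[id] != 0L) next
    path <- character(0)
    cur <- id
    while (!is.na(cur) && cur %in% ids && state[cur] == 0L) {
      state[cur] <- 1L
      path <- c(path, cur)
      cur <- par[[cur]]
    }
    if (!is.na(cur) && cur %in% ids && state[cur] == 1L)
      add(cur, "cycle", "parent links form a cycle")
    state[path] <- 2L
  }

  if (!length(rep))
    return(data.frame(rootId = character(0), type = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rep)
}

#' Translate a whole root system
#'
#' Rigid translation of every node of every root by `(dx, dy)` cm. Topology,
#' orders and insertion positions are unchanged.
#'
#' @param system a [RootSystem].
#' @param dx,dy translation in cm.
#' @return the translated [RootSystem].
#' @export
translateSystem <- function(system, dx, dy) {
  system@roots <- lapply(system@roots, function(r) {
    r@polyline[, "x"] <- r@polyline[, "x"] + dx
    r@polyline[, "y"] <- r@polyline[, "y"] + dy
    r
  })
  system
}

#' Attach a root to a parent
#'
#' Sets `parentId` of `childId` to `parentId`, computes the insertion
#' position as the arc length of the nearest point on the parent polyline to
#' the child's first node, and recomputes the branching order of the child
#' and its entire subtree as `parent order + depth`. This mirrors the manual
#' "attach to a common parent" step used when tracings from different scans
#' are connected.
#'
#' @param system a [RootSystem].
#' @param childId id of the root to attach.
#' @param parentId id of the new parent.
#' @return the updated [RootSystem].
#' @export
attachRoot <- function(system, childId, parentId) {
  if (!childId %in% names(system@roots)) stop("unknown root id: ", childId)
  if (!parentId %in% names(system@roots)) stop("unknown root id: ", parentId)
  if (childId == parentId ||
      parentId %in% descendantIds(system, childId))
    stop("attaching '", childId, "' under '", parentId,
         "' would create a cycle")
  parent <- system@roots[[parentId]]
  child <- system@roots[[childId]]
  hit <- nearestOnPolyline(parent@polyline, child@polyline[1, c("x", "y")])
  child@parentId <- parentId
  child@insertion <- unname(hit["arc"])
  child@order <- parent@order + 1L
  system@roots[[childId]] <- child
  # recompute subtree orders breadth-first
  frontier <- childId
  while (length(frontier)) {
    nxt <- character(0)
    for (id in frontier) {
      for (cid in childIds(system, id)) {
        system@roots[[cid]]@order <- system@roots[[id]]@order + 1L
        nxt <- c(nxt, cid)
      }
    }
    frontier <- nxt
  }
  maxOrd <- max(vapply(system@roots, function(r) r@order, integer(1)))
  if (maxOrd > 3L)
    stop("attachment would create a root of order ", maxOrd,
         " (maximum is 3)")
  system
}

#' Merge registered partial tracings into one root system
#'
#' Implements the combine step of split-and-combine scanning: every fragment
#' is translated by its registration offset into the common rhizotron frame,
#' all roots are pooled (ids suffixed on collision), and every parentless
#' lateral (order > 1, its parent was traced in another scan) is attached to
#' the nearest candidate parent of order one less, provided the distance
#' from the lateral's first node to the candidate polyline is at most
#' `attachTolerance`. Laterals with no candidate within tolerance are kept
#' as orphans and listed in the merge report, mirroring the interactive
#' correction step of the tracing workflow. No polyline is resampled, so
#' total length and surface are exactly conserved.
#'
#' @param parts non-empty list of [PartialTracing] objects.
#' @param attachTolerance maximum attachment distance in cm (default 0.5,
#'   about the registration accuracy of an acetate tracing).
#' @param label label of the merged system.
#' @return a [RootSystem]; the merge report (data.frame with columns
#'   `childId`, `parentId` — `"ORPHAN"` when unattached —, `distance`,
#'   `insertion`) is available via [mergeReport()].
#' @export
mergeTracings <- function(parts, attachTolerance = 0.5, label = "merged") {
  if (!length(parts)) stop("parts must be a non-empty list")
  if (!all(vapply(parts, is, logical(1), "PartialTracing")))
    stop("parts must be PartialTracing objects")

  roots <- list()
  for (k in seq_along(parts)) {
    frag <- translateSystem(parts[[k]]@system,
                            parts[[k]]@offset[1], parts[[k]]@offset[2])
    ids <- names(frag@roots)
    clash <- ids[ids %in% names(roots)]
    if (length(clash)) {
      ren <- setNames(paste0(clash, "#", k), clash)
      frag@roots <- lapply(frag@roots, function(r) {
        if (r@id %in% clash) r@id <- ren[[r@id]]
        if (!is.na(r@parentId) && r@parentId %in% clash)
          r@parentId <- ren[[r@parentId]]
        r
      })
      names(frag@roots) <- vapply(frag@roots, function(r) r@id, character(1))
    }
    roots <- c(roots, frag@roots)
  }

  ext <- Reduce(pmax, lapply(parts, function(p) p@system@extent))
  sys <- RootSystem(roots, label = label, extent = ext)

  orphans <- sort(names(sys@roots)[vapply(sys@roots, function(r)
    is.na(r@parentId) && r@order > 1L, logical(1))])
  report <- list()
  for (oid in orphans) {
    child <- sys@roots[[oid]]
    wanted <- child@order - 1L
    candidates <- names(sys@roots)[vapply(sys@roots, function(r)
      r@order == wanted, logical(1))]
    candidates <- setdiff(candidates, c(oid, descendantIds(sys, oid)))
    best <- NULL
    for (cid in sort(candidates)) {
      hit <- nearestOnPolyline(sys@roots[[cid]]@polyline,
                               child@polyline[1, c("x", "y")])
      if (is.null(best) || hit["distance"] < best$distance) {
        best <- list(id = cid, distance = unname(hit["distance"]),
                     arc = unname(hit["arc"]))
      }
    }
    if (!is.null(best) && best$distance <= attachTolerance) {
      sys <- attachRoot(sys, oid, best$id)
      report[[length(report) + 1L]] <- data.frame(
        childId = oid, parentId = best$id, distance = best$distance,
        insertion = sys@roots[[oid]]@insertion, stringsAsFactors = FALSE)
    } else {
      report[[length(report) + 1L]] <- data.frame(
        childId = oid, parentId = "ORPHAN",
        distance = if (is.null(best)) NA_real_ else best$distance,
        insertion = NA_real_, stringsAsFactors = FALSE)
    }
  }

  sys@metadata$mergeReport <- if (length(report)) do.call(rbind, report) else
    data.frame(childId = character(0), parentId = character(0),
               distance = numeric(0), insertion = numeric(0),
               stringsAsFactors = FALSE)
  sys
}

#' Merge report of a merged system
#'
#' @param system a [RootSystem] produced by [mergeTracings()].
#' @return data.frame with one row per lateral the merge had to attach:
#'   `childId`, `parentId` (`"ORPHAN"` if unattached), `distance`,
#'   `insertion`.
#' @export
mergeReport <- function(system) {
  rep <- system@metadata$mergeReport
  if (is.null(rep)) stop("system carries no merge report")
  rep
}
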
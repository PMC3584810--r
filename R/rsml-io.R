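# RSML 1.0 reading/writing and raster soil-grid I/O.
#
# RSML dialect: geometry as a per-root <polyline> of <point x= y=/> elements;
# per-node diameters as a polyline-domain <function name="diameter"> of
# <sample value=/> elements; laterals nested inside their parent <root>.
# Numbers are serialized with %.12g so that a write/read/write cycle is
# byte-identical and coordinates survive to well below 1e-9 cm.

.unitScale <- c(m = 100, dm = 10, cm = 1, mm = 0.1, um = 1e-4, "µm" = 1e-4,
                inch = 2.54)

.num <- function(x) sprintf("%.12g", x)

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

#' Read a root system from an RSML file
#'
#' Parses an RSML 1.0 document into a [RootSystem]. The declared unit must
#' resolve to centimeters (cm, mm, m, um, dm or inch); all coordinates and
#' diameters are rescaled to cm. Root order is taken from the nesting depth
#' (top level = order 1); nesting deeper than 3 is a format error. Missing
#' diameter samples default to the root's last seen diameter; a root with no
#' diameter information at all is a format error. Insertion positions of
#' nested laterals are recomputed as the arc-length projection of the
#' lateral's first node onto the parent polyline.
#'
#' @param path path to an RSML file.
#' @return a validated [RootSystem].
#' @seealso [writeRSML()]
#' @export
readRSML <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  unit <- xml2::xml_text(xml2::xml_find_first(doc, ".//metadata/unit"))
  if (is.na(unit) || !nzchar(unit))
    stop("RSML format error: missing unit declaration")
  if (!unit %in% names(.unitScale))
    stop("RSML format error: unknown unit '", unit, "'")
  scale <- .unitScale[[unit]]
  res <- xml2::xml_text(xml2::xml_find_first(doc, ".//metadata/resolution"))
  if (!is.na(res) && nzchar(res)) {
    res <- suppressWarnings(as.numeric(res))
    if (is.na(res) || !is.finite(res) || res <= 0)
      stop("RSML format error: resolution must be a positive number")
    scale <- scale * res
  }
  if (!is.finite(scale) || scale <= 0)
    stop("RSML format error: unit does not resolve to a positive cm scale")

  ext <- xml2::xml_find_first(doc, ".//metadata/extent")
  extent <- if (inherits(ext, "xml_node"))
    c(as.numeric(xml2::xml_attr(ext, "width")),
      as.numeric(xml2::xml_attr(ext, "height"))) * scale
  else c(50, 50)

  plant <- xml2::xml_find_first(doc, ".//scene/plant")
  label <- if (inherits(plant, "xml_node")) {
    lab <- xml2::xml_attr(plant, "label")
    if (is.na(lab)) "" else lab
  } else ""

  roots <- list()
  parseRoot <- function(node, depth, parentId) {
    if (depth > 3L)
      stop("RSML format error: root nesting depth exceeds 3")
    id <- xml2::xml_attr(node, "ID")
    if (is.na(id)) id <- xml2::xml_attr(node, "id")
    if (is.na(id)) id <- sprintf("root_%d", length(roots) + 1L)
    pts <- xml2::xml_find_all(node, "./geometry/polyline/point")
    if (!length(pts))
      stop("RSML format error: root '", id, "' has a polyline with no points")
    x <- as.numeric(xml2::xml_attr(pts, "x")) * scale
    y <- as.numeric(xml2::xml_attr(pts, "y")) * scale
    if (any(is.na(x)) || any(is.na(y)))
      stop("RSML format error: non-numeric coordinates in root '", id, "'")
    smp <- xml2::xml_find_all(
      node, "./functions/function[@name='diameter']/sample")
    d <- as.numeric(xml2::xml_attr(smp, "value"))
    if (!length(smp)) d <- numeric(0)
    if (any(is.na(d))) d <- as.numeric(xml2::xml_text(smp))
    if (!length(d) || any(is.na(d)))
      stop("RSML format error: root '", id, "' has no diameter annotation")
    n <- length(x)
    if (length(d) < n) d <- c(d, rep(d[length(d)], n - length(d)))
    d <- d[seq_len(n)] * scale

    roots[[id]] <<- Root(id, cbind(x = x, y = y, diameter = d),
                         order = depth, parentId = parentId,
                         insertion = NA_real_)
    for (child in xml2::xml_find_all(node, "./root"))
      parseRoot(child, depth + 1L, id)
  }
  if (inherits(plant, "xml_node"))
    for (top in xml2::xml_find_all(plant, "./root"))
      parseRoot(top, 1L, NA_character_)

  sys <- RootSystem(roots, label = label, extent = extent)
  # recover insertion positions by projection onto the parent polyline
  for (id in names(sys@roots)) {
    r <- sys@roots[[id]]
    if (!is.na(r@parentId)) {
      hit <- nearestOnPolyline(sys@roots[[r@parentId]]@polyline,
                               r@polyline[1, c("x", "y")])
      sys@roots[[id]]@insertion <- unname(hit["arc"])
    }
  }
  validObject(sys)
  sys
}

#' Write a root system to an RSML file
#'
#' Emits RSML 1.0 with unit cm, nesting each lateral inside its parent root
#' element and storing per-node diameters as a polyline-domain function.
#' The system must be topologically valid ([validateSystem()] empty) apart
#' from orphan laterals, which cannot be represented by nesting and are
#' rejected.
#'
#' @param system a [RootSystem].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRSML <- function(system, path) {
  rep <- validateSystem(system)
  if (nrow(rep))
    stop("refusing to write an invalid system: ",
         paste(unique(rep$message), collapse = "; "))
  out <- character(0)
  emit <- function(...) out[[length(out) + 1L]] <<- paste0(...)

  emitRoot <- function(id, indent) {
    r <- system@roots[[id]]
    pad <- strrep("  ", indent)
    emit(pad, '<root ID="', .xmlEscape(id), '" label="', .xmlEscape(id), '">')
    emit(pad, "  <geometry><polyline>")
    pl <- r@polyline
    for (i in seq_len(nrow(pl)))
      emit(pad, '    <point x="', .num(pl[i, "x"]), '" y="',
           .num(pl[i, "y"]), '"/>')
    emit(pad, "  </polyline></geometry>")
    emit(pad, '  <functions><function name="diameter" domain="polyline">')
    for (i in seq_len(nrow(pl)))
      emit(pad, '    <sample value="', .num(pl[i, "diameter"]), '"/>')
    emit(pad, "  </function></functions>")
    for (cid in sort(childIds(system, id)))
      emitRoot(cid, indent + 1L)
    emit(pad, "</root>")
  }

  emit('<?xml version="1.0" encoding="UTF-8"?>')
  emit("<rsml>")
  emit("  <metadata>")
  emit("    <version>1</version>")
  emit("    <unit>cm</unit>")
  emit("    <resolution>1</resolution>")
  emit("    <software>rhizovec</software>")
  emit('    <extent width="', .num(system@extent[1]), '" height="',
       .num(system@extent[2]), '"/>')
  emit("  </metadata>")
  emit("  <scene>")
  emit('    <plant id="1" label="', .xmlEscape(system@label), '">')
  top <- sort(names(system@roots)[vapply(system@roots, function(r)
    is.na(r@parentId), logical(1))])
  for (id in top) emitRoot(id, 3L)
  emit("    </plant>")
  emit("  </scene>")
  emit("</rsml>")
  writeLines(out, path, sep = "\n")
  invisible(path)
}

# ---- raster soil grids -----------------------------------------------------

.readKeyValue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "[ \t=]+")
  setNames(vapply(kv, function(p) paste(p[-1], collapse = " "), character(1)),
           vapply(kv, `[[`, character(1), 1L))
}

#' Read a soil water-content grid
#'
#' Two formats are supported. The native plain-text format has a 4-line
#' header (`origin_x`, `origin_y`, `pixel_size`, `timestamp`, each as
#' `key value`) followed by whitespace-separated matrix rows of values in
#' [0, 1]. Alternatively an 8-bit grayscale PNG is accepted, with intensities
#' mapped linearly to [0, 1] and the header supplied through a sidecar
#' key-value file (default `<path>.meta`).
#'
#' @param path grid file (`.png` triggers image mode).
#' @param sidecar sidecar header file for image mode.
#' @return a [SoilGrid].
#' @export
readSoilGrid <- function(path, sidecar = paste0(path, ".meta")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    hdr <- .readKeyValue(sidecar)
    vals <- img
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    hdrLines <- lines[1:4]
    kv <- strsplit(trimws(hdrLines), "[ \t=]+")
    hdr <- setNames(vapply(kv, `[[`, character(1), 2L),
                    vapply(kv, `[[`, character(1), 1L))
    body <- lines[-(1:4)]
    rows <- lapply(strsplit(trimws(body), "[ \t]+"), as.numeric)
    ncols <- unique(lengths(rows))
    if (length(ncols) != 1L)
      stop("grid format error in ", path, ": ragged rows")
    vals <- do.call(rbind, rows)
  }
  need <- c("origin_x", "origin_y", "pixel_size", "timestamp")
  if (!all(need %in% names(hdr)))
    stop("grid format error in ", path, ": header must provide ",
         paste(need, collapse = ", "))
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop("value error in ", path, ": water-content values outside [0, 1]")
  SoilGrid(vals,
           origin = as.numeric(hdr[c("origin_x", "origin_y")]),
           pixelSize = as.numeric(hdr[["pixel_size"]]),
           timestamp = as.numeric(hdr[["timestamp"]]))
}

#' Write a soil grid in the plain-text format
#'
#' @param grid a [SoilGrid].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSoilGrid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("origin_x", .num(grid@origin[1])),
               paste("origin_y", .num(grid@origin[2])),
               paste("pixel_size", .num(grid@pixelSize)),
               paste("timestamp", .num(grid@timestamp))), con)
  utils::write.table(grid@values, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a time series of soil grids
#'
#' Reads a set of grid files that must share dimensions, origin and pixel
#' size, optionally overriding their header timestamps, and returns them
#' sorted by time.
#'
#' @param paths character vector of grid files.
#' @param timestamps optional numeric vector of hours, same length as
#'   `paths`, overriding the file headers.
#' @return list of [SoilGrid], sorted by timestamp.
#' @export
loadSoilSeries <- function(paths, timestamps = NULL) {
  if (!length(paths)) stop("series error: no grid files given")
  if (!is.null(timestamps) && length(timestamps) != length(paths))
    stop("series error: length(paths) != length(timestamps)")
  grids <- lapply(paths, readSoilGrid)
  if (!is.null(timestamps))
    for (i in seq_along(grids)) grids[[i]]@timestamp <- timestamps[i]
  dims <- vapply(grids, function(g) dim(g@values), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("series error: grids differ in dimensions")
  orig <- vapply(grids, function(g) g@origin, numeric(2))
  px <- vapply(grids, function(g) g@pixelSize, numeric(1))
  if (any(abs(orig - orig[, 1]) > 1e-9) || any(abs(px - px[1]) > 1e-9))
    stop("series error: grids differ in origin or pixel size")
  ts <- vapply(grids, function(g) g@timestamp, numeric(1))
  if (anyDuplicated(ts))
    stop("series error: duplicate timestamps")
  grids[order(ts)]
}

#' Write a distance map
#'
#' The distance channel goes to the plain-text grid format (timestamp 0,
#' distances in cm — note these are not water contents and are not bounded
#' by 1); the nearest-root attributes go to a companion CSV with columns
#' `row`, `col`, `distance_cm`, `nearest_root`, `nearest_order`.
#'
#' @param dmap a [DistanceMap].
#' @param gridPath output path for the distance raster.
#' @param csvPath output path for the attribute table.
#' @return invisibly, `c(gridPath, csvPath)`.
#' @export
writeDistanceMap <- function(dmap, gridPath, csvPath) {
  con <- file(gridPath, "w")
  writeLines(c(paste("origin_x", .num(dmap@origin[1])),
               paste("origin_y", .num(dmap@origin[2])),
               paste("pixel_size", .num(dmap@pixelSize)),
               "timestamp 0"), con)
  utils::write.table(dmap@distance, con, row.names = FALSE, col.names = FALSE)
  close(con)
  idx <- expand.grid(row = seq_len(nrow(dmap@distance)),
                     col = seq_len(ncol(dmap@distance)))
  utils::write.csv(data.frame(
    row = idx$row, col = idx$col,
    distance_cm = dmap@distance[cbind(idx$row, idx$col)],
    nearest_root = dmap@nearestId[cbind(idx$row, idx$col)],
    nearest_order = dmap@nearestOrder[cbind(idx$row, idx$col)]),
    csvPath, row.names = FALSE)
  invisible(c(gridPath, csvPath))
}
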
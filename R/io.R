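#' Read and write rasters as ESRI ASCII grids
#'
#' Single-band plain-text raster I/O in the Arc/Info ASCII grid format
#' (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`/`NODATA_value` header
#' followed by rows north to south). This is the package's raster interchange
#' format; the CRS tag is carried in a `# crs:` comment line that other
#' readers ignore.
#'
#' @param path File path.
#' @return `read_ascii_grid` returns an [eco_grid].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 8L)
  crs <- "local"
  hdr <- list(); i <- 0L
  for (ln in lines) {
    if (grepl("^#", ln)) {
      m <- regmatches(ln, regexec("^#\\s*crs:\\s*(.+)$", ln))[[1]]
      if (length(m) == 2L) crs <- trimws(m[2])
      i <- i + 1L
      next
    }
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr))) stop("malformed ASCII grid header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, what = double(), skip = i, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) stop("ASCII grid body size mismatch in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  eco_grid(m, origin_x = hdr$xllcorner,
           origin_y = hdr$yllcorner + nr * hdr$cellsize,
           cell_size = hdr$cellsize, crs_tag = crs)
}

#' @rdname read_ascii_grid
#' @param grid An [eco_grid] to write.
#' @param nodata Numeric value encoding masked cells on disk.
#' @param digits Significant digits used when formatting cell values.
#' @return `write_ascii_grid` returns `path` invisibly.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999, digits = 10) {
  if (!inherits(grid, "eco_grid")) stop("'grid' must be an eco_grid")
  gm <- grid$geometry
  v <- grid$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", gm$ncol),
    sprintf("nrows %d", gm$nrow),
    sprintf("xllcorner %.10g", gm$origin_x),
    sprintf("yllcorner %.10g", gm$origin_y - gm$nrow * gm$cell_size),
    sprintf("cellsize %.10g", gm$cell_size),
    sprintf("NODATA_value %.10g", nodata),
    sprintf("# crs: %s", gm$crs_tag)
  ), con)
  for (r in seq_len(gm$nrow))
    writeLines(paste(formatC(v[r, ], format = "g", digits = digits),
                     collapse = " "), con)
  invisible(path)
}

#' Read vegetation-occurrence features from GeoJSON
#'
#' Parses a GeoJSON FeatureCollection of `Polygon`, `MultiPolygon` or `Point`
#' features, each carrying a `veg_type` string property, into the simple
#' feature list consumed by [rasterize_occurrences()].
#'
#' @param path Path to a GeoJSON file.
#' @return A list of class `eco_features`; each element has `type`
#'   (`"polygon"` or `"point"`), `veg_type`, and either `rings` (list of
#'   two-column coordinate matrices, outer rings and holes) or `x`/`y`.
#' @export
read_geojson <- function(path) {
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(js$features)) stop("not a GeoJSON FeatureCollection: ", path)
  feats <- lapply(js$features, function(f) {
    vt <- f$properties$veg_type
    if (is.null(vt)) vt <- NA_character_
    g <- f$geometry
    ring_mat <- function(ring)
      matrix(unlist(ring), ncol = 2, byrow = TRUE)
    switch(g$type,
      Point = list(type = "point", veg_type = vt,
                   x = g$coordinates[[1]], y = g$coordinates[[2]]),
      Polygon = list(type = "polygon", veg_type = vt,
                     rings = lapply(g$coordinates, ring_mat)),
      MultiPolygon = list(type = "polygon", veg_type = vt,
                          rings = unlist(lapply(g$coordinates, function(p)
                            lapply(p, ring_mat)), recursive = FALSE)),
      stop("unsupported GeoJSON geometry type: ", g$type))
  })
  structure(feats, class = "eco_features")
}

# shared scaffolding for GeoJSON output
geojson_feature <- function(geometry, properties = list())
  list(type = "feature", geometry = geometry, properties = properties)

write_geojson_features <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = lapply(features, function(f)
    list(type = "Feature", geometry = f$geometry, properties = f$properties)))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

coords_list <- function(mat) lapply(seq_len(nrow(mat)), function(i)
  c(mat[i, 1], mat[i, 2]))

#' Convert package objects to GeoJSON and write them
#'
#' `as_geojson()` renders a [extract_boundary()] boundary set (as
#' `MultiLineString`), a [compose_transition()] transition zone (band polygon
#' plus its north/south envelope lines), or a graded quadrat data frame (as
#' `Point` features) into GeoJSON structures; `write_geojson()` serializes
#' them to a file.
#'
#' @param x A `boundary_set`, `eco_transition`, or quadrat data frame with
#'   `x`/`y` columns.
#' @param ... Unused.
#' @return `as_geojson` returns a list of feature structures;
#'   `write_geojson` writes and returns the path invisibly.
#' @export
as_geojson <- function(x, ...) UseMethod("as_geojson")

#' @export
as_geojson.boundary_set <- function(x, ...) {
  list(geojson_feature(
    list(type = "MultiLineString",
         coordinates = lapply(x$lines, coords_list)),
    list(pair = if (!is.null(x$pair)) x$pair$group_id else NA,
         total_length = x$total_length)))
}

#' @export
as_geojson.eco_transition <- function(x, ...) {
  feats <- list(geojson_feature(
    list(type = "Polygon", coordinates = list(coords_list(x$polygon))),
    list(zone = "transition", mean_width = x$mean_width)))
  feats[[2]] <- geojson_feature(
    list(type = "LineString", coordinates = coords_list(x$north_boundary)),
    list(envelope = "north"))
  feats[[3]] <- geojson_feature(
    list(type = "LineString", coordinates = coords_list(x$south_boundary)),
    list(envelope = "south"))
  feats
}

#' @export
as_geojson.data.frame <- function(x, ...) {
  stopifnot(all(c("x", "y") %in% names(x)))
  props <- setdiff(names(x), c("x", "y"))
  lapply(seq_len(nrow(x)), function(i)
    geojson_feature(list(type = "Point", coordinates = c(x$x[i], x$y[i])),
                    as.list(x[i, props, drop = FALSE])))
}

#' @rdname as_geojson
#' @param path Output file path.
#' @export
write_geojson <- function(x, path, ...)
  write_geojson_features(as_geojson(x, ...), path)
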
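#' Compose several pairs' boundaries into a transition zone
#'
#' Builds the transition band swept by the boundary polylines of two or more
#' vegetation pairs. Per raster column (west to east), the crossings of every
#' boundary polyline with the column-center vertical line are collected; the
#' northernmost and southernmost crossings over all sets are the band
#' envelopes, and the band is every pixel row between them (inclusive of the
#' rows the envelope edges touch on their south side). Pixels north of the
#' band are temperate, south subtropical. Columns crossed by no boundary are
#' filled by nearest-column copy of the envelopes (ties to the west) and are
#' excluded from the mean width. Coincident boundaries yield a 1-cell band,
#' so the three-zone partition always exists.
#'
#' @param boundaries List of [extract_boundary()] results (at least 2
#'   non-empty sets).
#' @param geometry Target grid geometry the partition is rendered on.
#' @param mask Optional logical matrix (TRUE = masked) applied to the
#'   partition.
#' @return An object of class `eco_transition`:
#'   \describe{
#'     \item{partition}{`eco_partition`: integer matrix in \{0 subtropical,
#'       1 transition, 2 temperate, -1 masked\} plus geometry.}
#'     \item{north_boundary, south_boundary}{Envelope polylines (map coords).}
#'     \item{width_profile}{Per-column band extent, map units.}
#'     \item{mean_width}{Mean of `width_profile` over interpolation-free
#'       columns.}
#'     \item{polygon}{Closed band outline in map coordinates.}
#'     \item{interpolated}{Logical, per column.}
#'   }
#' @export
compose_transition <- function(boundaries, geometry, mask = NULL) {
  if (inherits(boundaries, "boundary_set")) boundaries <- list(boundaries)
  nonempty <- vapply(boundaries, function(b) length(b$lines) > 0L, logical(1))
  if (!any(nonempty)) stop("all boundary sets are empty")
  if (sum(nonempty) < 2L)
    warning("fewer than 2 non-empty boundary sets; band degenerates to one boundary")
  boundaries <- boundaries[nonempty]
  gm <- geometry
  nc <- gm$ncol; nr <- gm$nrow
  xs <- pixel_center_x(gm, seq_len(nc))
  # fractional-row crossing of every segment with every column-center line
  fr_min <- rep(NA_real_, nc)   # northernmost crossing (smallest frac row)
  fr_max <- rep(NA_real_, nc)
  for (bs in boundaries) for (ln in bs$lines) {
    if (nrow(ln) < 2L) next
    for (s in seq_len(nrow(ln) - 1L)) {
      x1 <- ln[s, 1]; x2 <- ln[s + 1L, 1]
      if (x1 == x2) next                      # vertical edge: between columns
      xlo <- min(x1, x2); xhi <- max(x1, x2)
      j <- which(xs > xlo & xs < xhi)
      if (!length(j)) next
      y1 <- ln[s, 2]; y2 <- ln[s + 1L, 2]
      ycross <- y1 + (xs[j] - x1) * (y2 - y1) / (x2 - x1)
      fr <- (gm$origin_y - ycross) / gm$cell_size
      fr_min[j] <- pmin(fr_min[j], fr, na.rm = TRUE)
      fr_max[j] <- pmax(fr_max[j], fr, na.rm = TRUE)
    }
  }
  has <- !is.na(fr_min)
  if (!any(has)) stop("no boundary crosses any raster column")
  interp <- !has
  if (any(interp)) {
    src <- which(has)
    for (j in which(interp)) {
      d <- abs(src - j)
      k <- src[which.min(d)]                  # which.min ties to the west
      fr_min[j] <- fr_min[k]; fr_max[j] <- fr_max[k]
    }
  }
  r1 <- pmin(pmax(floor(fr_min) + 1, 1), nr)  # first (northern) band row
  r2 <- pmin(pmax(floor(fr_max) + 1, 1), nr)  # last (southern) band row
  zones <- matrix(0L, nr, nc)                 # default subtropical (south)
  rows <- seq_len(nr)
  for (j in seq_len(nc)) {
    zones[rows < r1[j], j] <- 2L
    zones[rows >= r1[j] & rows <= r2[j], j] <- 1L
  }
  if (!is.null(mask)) zones[mask] <- -1L
  width_profile <- (r2 - r1 + 1) * gm$cell_size
  mean_width <- mean(width_profile[!interp])
  yN <- gm$origin_y - fr_min * gm$cell_size
  yS <- gm$origin_y - fr_max * gm$cell_size
  north <- cbind(x = xs, y = yN)
  south <- cbind(x = xs, y = yS)
  polygon <- rbind(north, south[rev(seq_len(nc)), , drop = FALSE], north[1, ])
  structure(list(
    partition = structure(list(values = zones, geometry = gm),
                          class = "eco_partition"),
    north_boundary = north, south_boundary = south,
    width_profile = width_profile, mean_width = mean_width,
    polygon = polygon, interpolated = interp, geometry = gm),
    class = "eco_transition")
}

#' @export
print.eco_transition <- function(x, ...) {
  cat(sprintf("<eco_transition> mean width %.2f map units (%d of %d columns interpolated)\n",
              x$mean_width, sum(x$interpolated), length(x$interpolated)))
  print(x$partition)
  invisible(x)
}

#' @export
print.eco_partition <- function(x, ...) {
  tb <- table(factor(x$values, levels = c(-1, 0, 1, 2)))
  cat(sprintf("<eco_partition> masked %d | subtropical %d | transition %d | temperate %d\n",
              tb[["-1"]], tb[["0"]], tb[["1"]], tb[["2"]]))
  invisible(x)
}

# partition -> eco_grid (for ASCII output); masked cells become NA
partition_grid <- function(partition) {
  v <- partition$values
  v[v == -1L] <- NA_integer_
  g <- eco_grid(matrix(as.numeric(v), nrow(v), ncol(v)),
                origin_x = partition$geometry$origin_x,
                origin_y = partition$geometry$origin_y,
                cell_size = partition$geometry$cell_size,
                crs_tag = partition$geometry$crs_tag)
  g
}
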
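#' Vegetation pair specification
#'
#' Names the subtropical and temperate member of one indicator-vegetation
#' pair (e.g. the subtropical and temperate pine forests used to delimit the
#' coniferous-forest boundary).
#'
#' @param group_id Short identifier, e.g. `"I"`, `"II"`, `"III"`.
#' @param subtropical_name,temperate_name Distinct vegetation type names as
#'   they appear in the occurrence data's `veg_type` attribute.
#' @return An object of class `pair_spec`.
#' @export
pair_spec <- function(group_id, subtropical_name, temperate_name) {
  if (identical(subtropical_name, temperate_name))
    stop("the two vegetation names of a pair must be distinct")
  structure(list(group_id = as.character(group_id),
                 subtropical_name = as.character(subtropical_name),
                 temperate_name = as.character(temperate_name)),
            class = "pair_spec")
}

#' @export
print.pair_spec <- function(x, ...) {
  cat(sprintf("<pair %s> subtropical: %s | temperate: %s\n",
              x$group_id, x$subtropical_name, x$temperate_name))
  invisible(x)
}

#' Per-pixel vegetation labels for one pair
#'
#' @param labels Integer matrix matching the grid geometry; -1 = absent,
#'   0 = subtropical member present, 1 = temperate member present.
#' @param pair A [pair_spec()].
#' @param geometry Shared grid geometry (see [grid_geometry()]).
#' @return An object of class `veg_occurrence`.
#' @export
veg_occurrence <- function(labels, pair, geometry) {
  if (!is.matrix(labels)) stop("'labels' must be a matrix")
  if (!all(labels %in% c(-1L, 0L, 1L))) stop("labels must be in {-1, 0, 1}")
  storage.mode(labels) <- "integer"
  if (geometry$nrow != nrow(labels) || geometry$ncol != ncol(labels))
    stop("labels shape does not match geometry")
  structure(list(labels = labels, pair = pair, geometry = geometry),
            class = "veg_occurrence")
}

#' @export
print.veg_occurrence <- function(x, ...) {
  tb <- table(factor(x$labels, levels = c(-1, 0, 1)))
  cat(sprintf("<veg_occurrence pair %s> absent %d | subtropical %d | temperate %d\n",
              x$pair$group_id, tb[["-1"]], tb[["0"]], tb[["1"]]))
  invisible(x)
}

# TRUE for pixel centers inside any ring set (even-odd rule via mgcv::in.out)
centers_in_polygon <- function(gm, rings) {
  bnd <- do.call(rbind, lapply(rings, function(r) rbind(r, c(NA, NA))))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  xs <- pixel_center_x(gm, seq_len(gm$ncol))
  ys <- pixel_center_y(gm, seq_len(gm$nrow))
  pts <- cbind(rep(xs, each = gm$nrow), rep(ys, times = gm$ncol))
  matrix(mgcv::in.out(bnd, pts), gm$nrow, gm$ncol)
}

#' Rasterize vegetation occurrences onto a grid
#'
#' Burns polygon or point features of a vegetation pair into a label raster:
#' a pixel whose center falls inside a feature of the pair's subtropical
#' (resp. temperate) member gets label 0 (resp. 1); every other pixel -1.
#' Pixel-center containment decides polygons; a point labels its containing
#' pixel. A pixel claimed by both classes is set back to -1 (excluded), so
#' mixed pixels never feed label noise into training.
#'
#' @param features An `eco_features` list (see [read_geojson()]) or a data
#'   frame with columns `x`, `y`, `veg_type` (point features).
#' @param geometry Target grid geometry.
#' @param pair A [pair_spec()]; features are matched on `veg_type`.
#' @return A [veg_occurrence()].
#' @export
rasterize_occurrences <- function(features, geometry, pair) {
  if (is.data.frame(features)) {
    stopifnot(all(c("x", "y", "veg_type") %in% names(features)))
    features <- lapply(seq_len(nrow(features)), function(i)
      list(type = "point", veg_type = features$veg_type[i],
           x = features$x[i], y = features$y[i]))
  }
  gm <- geometry
  burn <- function(class_name) {
    hit <- matrix(FALSE, gm$nrow, gm$ncol)
    any_feat <- FALSE
    for (f in features) {
      if (!identical(f$veg_type, class_name)) next
      any_feat <- TRUE
      if (f$type == "polygon") {
        hit <- hit | centers_in_polygon(gm, f$rings)
      } else {
        rc <- point_to_rowcol(gm, f$x, f$y)
        if (!is.na(rc[1, 1])) hit[rc[1, 1], rc[1, 2]] <- TRUE
      }
    }
    if (!any_feat)
      stop(sprintf("unusable pair: no feature of class '%s'", class_name))
    hit
  }
  sub <- burn(pair$subtropical_name)
  tem <- burn(pair$temperate_name)
  lab <- matrix(-1L, gm$nrow, gm$ncol)
  lab[sub] <- 0L
  lab[tem] <- 1L
  lab[sub & tem] <- -1L   # mixed pixels excluded
  veg_occurrence(lab, pair, gm)
}

#' Extract labeled training pixels from a stack
#'
#' Builds the classifier / q-statistic sample: one row per pixel whose label
#' is 0 or 1 and whose value is non-masked in every requested covariate.
#' Rows are in row-major pixel order (north to south, west to east within a
#' row).
#'
#' @param stack A [covariate_stack()].
#' @param occ A [veg_occurrence()] on the same geometry.
#' @param variables Character vector of layer names to extract.
#' @return A list with `features` (numeric matrix, one column per variable),
#'   `labels` (integer 0/1 vector) and `pixels` (row-major linear pixel
#'   indices of the surviving rows).
#' @export
extract_labeled_pixels <- function(stack, occ, variables) {
  if (!inherits(stack, "eco_stack")) stop("'stack' must be an eco_stack")
  if (!inherits(occ, "veg_occurrence")) stop("'occ' must be a veg_occurrence")
  missing_v <- setdiff(variables, names(stack$layers))
  if (length(missing_v))
    stop("variables not in stack: ", paste(missing_v, collapse = ", "))
  if (!same_geometry(stack$geometry, occ$geometry))
    stop("occurrence geometry does not match stack")
  gm <- stack$geometry
  lab <- occ$labels
  pos <- which(lab >= 0L)                       # column-major positions
  if (length(pos) == 0L) stop("no training pixels: no labeled pixel survives")
  r <- (pos - 1L) %% gm$nrow + 1L
  c <- (pos - 1L) %/% gm$nrow + 1L
  rm_idx <- (r - 1L) * gm$ncol + c              # row-major order
  o <- order(rm_idx)
  pos <- pos[o]; rm_idx <- rm_idx[o]
  X <- vapply(variables, function(v) stack$layers[[v]]$values[pos],
              numeric(length(pos)))
  if (length(pos) == 1L) X <- matrix(X, nrow = 1L, dimnames = list(NULL, variables))
  keep <- rowSums(is.na(X)) == 0L
  if (!any(keep)) stop("no training pixels: all labeled pixels are masked")
  list(features = X[keep, , drop = FALSE],
       labels = as.integer(lab[pos][keep]),
       pixels = rm_idx[keep])
}
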
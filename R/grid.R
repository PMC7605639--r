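#' Georeferenced raster grid
#'
#' A minimal in-memory raster: a numeric matrix stored north-up (row 1 is the
#' northernmost row), a north-west corner origin in map coordinates, a square
#' cell size, and an opaque CRS tag. Masked (nodata) cells are `NA`; they never
#' enter any statistic computed by the package.
#'
#' @param values Numeric matrix, row 1 = north. `NA` marks nodata.
#' @param origin_x,origin_y Map coordinates of the north-west corner.
#'   Defaults place the grid in a local frame with the NW corner at
#'   `(0, nrow * cell_size)`, so map y increases northwards.
#' @param cell_size Positive scalar cell edge length (square cells), in map
#'   units.
#' @param crs_tag Opaque string naming the coordinate reference system.
#'   Alignment checks require equal tags; no reprojection is ever attempted.
#' @return An object of class `eco_grid`: a list with elements `values` and
#'   `geometry`.
#' @examples
#' g <- eco_grid(matrix(1:12, 3, 4))
#' grid_geometry(g)
#' @export
eco_grid <- function(values, origin_x = 0,
                     origin_y = nrow(values) * cell_size,
                     cell_size = 1, crs_tag = "local") {
  if (!is.matrix(values) || !(is.numeric(values) || is.logical(values)))
    stop("'values' must be a numeric matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0)
    stop("'cell_size' must be a positive scalar")
  storage.mode(values) <- "double"
  structure(list(
    values = values,
    geometry = list(nrow = nrow(values), ncol = ncol(values),
                    origin_x = as.numeric(origin_x),
                    origin_y = as.numeric(origin_y),
                    cell_size = as.numeric(cell_size),
                    crs_tag = as.character(crs_tag))
  ), class = "eco_grid")
}

#' @rdname eco_grid
#' @param g An `eco_grid` (or any object carrying a `$geometry`).
#' @export
grid_geometry <- function(g) {
  if (!is.null(g$geometry)) g$geometry else stop("object has no geometry")
}

#' @export
print.eco_grid <- function(x, ...) {
  gm <- x$geometry
  cat(sprintf("<eco_grid> %d x %d cells, cell %g, NW corner (%g, %g), crs '%s'\n",
              gm$nrow, gm$ncol, gm$cell_size, gm$origin_x, gm$origin_y, gm$crs_tag))
  cat(sprintf("  values: [%g, %g], %d masked\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE)),
              sum(is.na(x$values))))
  invisible(x)
}

# geometry equality to an absolute tolerance (1e-9 on origins/cell size)
same_geometry <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$origin_x - b$origin_x) <= tol &&
    abs(a$origin_y - b$origin_y) <= tol &&
    abs(a$cell_size - b$cell_size) <= tol &&
    identical(a$crs_tag, b$crs_tag)
}

# map coordinates of pixel centers; 1-based row/col
pixel_center_x <- function(gm, col) gm$origin_x + (col - 0.5) * gm$cell_size
pixel_center_y <- function(gm, row) gm$origin_y - (row - 0.5) * gm$cell_size

# containing pixel of a map point; NA outside the extent
point_to_rowcol <- function(gm, x, y) {
  col <- floor((x - gm$origin_x) / gm$cell_size) + 1
  row <- floor((gm$origin_y - y) / gm$cell_size) + 1
  bad <- col < 1 | col > gm$ncol | row < 1 | row > gm$nrow
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Stack of co-registered covariate layers
#'
#' Bundles named [eco_grid] layers that share geometry exactly (shape, origin
#' within 1e-9, cell size, CRS tag). The stack is the classifier feature space
#' and the sample source for the q-statistic.
#'
#' @param layers Named list of `eco_grid` objects (or several grids passed via
#'   `...`). Names must be unique.
#' @param ... Alternatively, named `eco_grid` arguments.
#' @return An object of class `eco_stack` with elements `layers` (named list)
#'   and `geometry` (the shared geometry).
#' @seealso [assert_aligned()]
#' @export
covariate_stack <- function(layers = NULL, ...) {
  if (is.null(layers)) layers <- list(...)
  if (length(layers) < 1L) stop("at least one layer is required")
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("layers must have unique, non-empty names")
  ok <- vapply(layers, inherits, logical(1), "eco_grid")
  if (!all(ok)) stop("all layers must be eco_grid objects")
  st <- structure(list(layers = layers, geometry = layers[[1]]$geometry),
                  class = "eco_stack")
  assert_aligned(st)
}

#' @export
print.eco_stack <- function(x, ...) {
  gm <- x$geometry
  cat(sprintf("<eco_stack> %d layers on %d x %d grid (cell %g, crs '%s')\n",
              length(x$layers), gm$nrow, gm$ncol, gm$cell_size, gm$crs_tag))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' Assert that all layers of a stack share one geometry
#'
#' Returns the stack unchanged iff every layer shares the geometry of the
#' first layer (same shape, origins within 1e-9, same CRS tag); otherwise
#' raises an error naming the first offending layer.
#'
#' @param stack An [covariate_stack()] object.
#' @return The stack, invisibly unchanged.
#' @export
assert_aligned <- function(stack) {
  if (!inherits(stack, "eco_stack")) stop("'stack' must be an eco_stack")
  ref <- stack$layers[[1]]$geometry
  for (nm in names(stack$layers)) {
    gm <- stack$layers[[nm]]$geometry
    if (!same_geometry(ref, gm))
      stop(sprintf("layer '%s' is not aligned with layer '%s'",
                   nm, names(stack$layers)[1]))
  }
  stack
}

#' Mean-aggregation resampling of a grid
#'
#' Coarsens a grid by an integer factor: each output cell is the mean of the
#' non-masked input cells in its `factor` x `factor` block (e.g. averaging
#' fine elevation into 1-km pixels). Fully masked blocks stay masked. Partial
#' blocks at the south/east edge average whatever cells exist. The cell size
#' is multiplied by `factor`; the NW origin is unchanged.
#'
#' @param grid An [eco_grid].
#' @param factor Positive integer aggregation factor; `1` is the identity.
#' @return An `eco_grid` with shape `ceiling(dim/factor)`.
#' @examples
#' aggregate_mean(eco_grid(matrix(c(1, 3, 2, 4), 2, 2)), 2)$values
#' @export
aggregate_mean <- function(grid, factor) {
  if (!inherits(grid, "eco_grid")) stop("'grid' must be an eco_grid")
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor < 1 || factor != round(factor))
    stop("'factor' must be a positive integer")
  f <- as.integer(factor)
  if (f == 1L) return(grid)
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  onr <- ceiling(nr / f); onc <- ceiling(nc / f)
  br <- ceiling(seq_len(nr) / f)           # output block row of each input row
  bc <- ceiling(seq_len(nc) / f)
  grp <- outer(br, bc, function(r, c) (c - 1L) * onr + r)
  vv <- as.vector(v); gg <- as.vector(grp)
  sums <- rowsum(ifelse(is.na(vv), 0, vv), gg)
  cnts <- rowsum(as.numeric(!is.na(vv)), gg)
  out <- rep(NA_real_, onr * onc)
  ids <- as.integer(rownames(sums))
  m <- sums[, 1] / pmax(cnts[, 1], 1)
  m[cnts[, 1] == 0] <- NA_real_
  out[ids] <- m
  gm <- grid$geometry
  eco_grid(matrix(out, onr, onc), origin_x = gm$origin_x, origin_y = gm$origin_y,
           cell_size = gm$cell_size * f, crs_tag = gm$crs_tag)
}
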
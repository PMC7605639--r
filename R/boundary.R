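#' Extract the inter-zone boundary polylines of a zone map
#'
#' Marches along 4-connectivity pixel edges: every edge shared by a 0-pixel
#' and a 1-pixel contributes one unit segment, and segments are chained into
#' maximal connected polylines (chains break at junction corners where more
#' than two segments meet). Coordinates are the edge lines in map units.
#' Edges adjacent to masked pixels are not boundary.
#'
#' @param zonemap An `eco_zonemap` (or any list with integer `values` in
#'   \{-1,0,1\} and a `geometry`).
#' @return An object of class `boundary_set`: `lines` (list of two-column
#'   coordinate matrices), `total_length` (map units), `n_segments`, `pair`.
#'   A single-class map yields an empty set with a warning.
#' @export
extract_boundary <- function(zonemap) {
  z <- zonemap$values
  gm <- zonemap$geometry
  nr <- nrow(z); nc <- ncol(z)
  if (!any(z == 0L) || !any(z == 1L)) {
    warning("zone map contains a single class; boundary set is empty")
    return(structure(list(lines = list(), total_length = 0, n_segments = 0L,
                          pair = zonemap$pair, geometry = gm),
                     class = "boundary_set"))
  }
  # corner lattice: i in 0..nc (x direction), j in 0..nr; id = j*(nc+1)+i+1
  cid <- function(i, j) j * (nc + 1L) + i + 1L
  segs_a <- integer(0); segs_b <- integer(0)
  if (nc > 1L) {                     # vertical edges between (r,c) and (r,c+1)
    a <- z[, -nc, drop = FALSE]; b <- z[, -1, drop = FALSE]
    w <- which((a == 0L & b == 1L) | (a == 1L & b == 0L), arr.ind = TRUE)
    if (nrow(w)) {
      segs_a <- c(segs_a, cid(w[, 2], w[, 1] - 1L))
      segs_b <- c(segs_b, cid(w[, 2], w[, 1]))
    }
  }
  if (nr > 1L) {                     # horizontal edges between (r,c) and (r+1,c)
    a <- z[-nr, , drop = FALSE]; b <- z[-1, , drop = FALSE]
    w <- which((a == 0L & b == 1L) | (a == 1L & b == 0L), arr.ind = TRUE)
    if (nrow(w)) {
      segs_a <- c(segs_a, cid(w[, 2] - 1L, w[, 1]))
      segs_b <- c(segs_b, cid(w[, 2], w[, 1]))
    }
  }
  m <- length(segs_a)
  # deterministic ordering of segments by (min corner, max corner)
  lo <- pmin(segs_a, segs_b); hi <- pmax(segs_a, segs_b)
  o <- order(lo, hi)
  lo <- lo[o]; hi <- hi[o]
  inc <- split(rep(seq_len(m), 2L), c(lo, hi))   # corner -> incident segments
  deg <- lengths(inc)
  used <- logical(m)
  other_end <- function(s, corner) if (lo[s] == corner) hi[s] else lo[s]
  walk <- function(start) {
    path <- start; cur <- start
    repeat {
      key <- as.character(cur)
      cand <- inc[[key]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      if (length(path) > 1L && deg[[key]] != 2L) break   # junction: stop chain
      s <- cand[1]
      used[s] <<- TRUE
      cur <- other_end(s, cur)
      path <- c(path, cur)
    }
    path
  }
  corners <- as.integer(names(inc))
  starts <- corners[deg[as.character(corners)] != 2L]
  lines <- list()
  for (st in sort(starts)) {
    repeat {
      cand <- inc[[as.character(st)]]
      if (all(used[cand])) break
      lines[[length(lines) + 1L]] <- walk(st)
    }
  }
  for (st in sort(corners)) {        # remaining closed loops
    cand <- inc[[as.character(st)]]
    if (all(used[cand])) next
    lines[[length(lines) + 1L]] <- walk(st)
  }
  to_xy <- function(ids) {
    i <- (ids - 1L) %% (nc + 1L)
    j <- (ids - 1L) %/% (nc + 1L)
    cbind(x = gm$origin_x + i * gm$cell_size,
          y = gm$origin_y - j * gm$cell_size)
  }
  structure(list(lines = lapply(lines, to_xy),
                 total_length = m * gm$cell_size,
                 n_segments = m, pair = zonemap$pair, geometry = gm),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("<boundary_set%s> %d polyline(s), %d segments, total length %g\n",
              if (!is.null(x$pair)) paste0(" pair ", x$pair$group_id) else "",
              length(x$lines), x$n_segments, x$total_length))
  invisible(x)
}
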
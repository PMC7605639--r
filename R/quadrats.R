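#' Count-grading bins for quadrat survey species
#'
#' Defines, per indicator species, the three inclusive stem-count intervals
#' (low / moderate / high) used to grade 20 m x 20 m quadrat records before
#' overlaying them on the zone partition. Counts below the lowest or above
#' the highest interval are left ungraded and excluded from overlays.
#'
#' @param species Species name.
#' @param low,moderate,high Length-2 integer vectors `c(lo, hi)`; the three
#'   intervals must be disjoint and ordered.
#' @return A one-species `grade_bins` list; combine with `c()`.
#' @export
grade_bins <- function(species, low, moderate, high) {
  iv <- rbind(low = low, moderate = moderate, high = high)
  if (any(iv[, 1] > iv[, 2])) stop("each interval must satisfy lo <= hi")
  if (!(iv[1, 2] < iv[2, 1] && iv[2, 2] < iv[3, 1]))
    stop("intervals must be disjoint and ordered low < moderate < high")
  b <- list(list(species = species, intervals = iv))
  names(b) <- species
  structure(b, class = "grade_bins_set")
}

#' @rdname grade_bins
#' @details `default_grade_bins()` returns the grading used for the three
#'   Qinling-Daba indicator species: Platycarya strobilacea and Pinus
#'   massoniana
#'   (subtropical indicators) graded low 2-3, moderate 4-10, high 11-98;
#'   Pinus tabuliformis (temperate indicator) graded low 2-10, moderate
#'   11-20, high 21-60.
#' @export
default_grade_bins <- function() {
  structure(c(
    grade_bins("Platycarya strobilacea", c(2, 3), c(4, 10), c(11, 98)),
    grade_bins("Pinus massoniana", c(2, 3), c(4, 10), c(11, 98)),
    grade_bins("Pinus tabuliformis", c(2, 10), c(11, 20), c(21, 60))
  ), class = "grade_bins_set")
}

#' Indicator roles of the default survey species
#'
#' Which climate zone each indicator species marks; used by
#' [overlay_consistency()].
#' @return Named character vector, values `"subtropical"` or `"temperate"`.
#' @export
default_indicator_roles <- function() {
  c("Platycarya strobilacea" = "subtropical",
    "Pinus massoniana" = "subtropical",
    "Pinus tabuliformis" = "temperate")
}

#' Grade quadrat survey records
#'
#' Assigns each record exactly one of `low`, `moderate`, `high`, `ungraded`
#' by inclusive interval membership of its stem count. Records of species
#' without bins are ungraded with a warning.
#'
#' @param records Data frame with columns `species` and `count`
#'   (non-negative integers); typically also `x`, `y`.
#' @param bins A `grade_bins_set`, default [default_grade_bins()].
#' @return `records` with a `grade` factor column added.
#' @export
grade_quadrats <- function(records, bins = default_grade_bins()) {
  stopifnot(all(c("species", "count") %in% names(records)))
  if (any(records$count < 0)) stop("counts must be non-negative")
  grade <- rep("ungraded", nrow(records))
  unknown <- setdiff(unique(records$species), names(bins))
  if (length(unknown))
    warning("no grading bins for species: ", paste(unknown, collapse = ", "))
  for (sp in intersect(unique(records$species), names(bins))) {
    iv <- bins[[sp]]$intervals
    sel <- records$species == sp
    cnt <- records$count[sel]
    g <- rep("ungraded", length(cnt))
    for (lev in rownames(iv))
      g[cnt >= iv[lev, 1] & cnt <= iv[lev, 2]] <- lev
    grade[sel] <- g
  }
  records$grade <- factor(grade, levels = c("low", "moderate", "high",
                                            "ungraded"))
  records
}

#' Overlay graded quadrats on the three-zone partition
#'
#' Assigns each graded record to the zone of its containing pixel and
#' tabulates species x grade x zone counts. For each indicator species a
#' descriptive consistency fraction is reported: the share of its graded
#' quadrats falling in the zones its role predicts (subtropical indicators
#' in the subtropical + transition zones, temperate indicators in the
#' temperate + transition zones). Records outside the raster extent or on
#' masked pixels are skipped with a warning; ungraded records are excluded.
#'
#' @param records Graded records from [grade_quadrats()] with `x`, `y`
#'   columns.
#' @param partition An `eco_partition`.
#' @param roles Named character vector mapping species to
#'   `"subtropical"`/`"temperate"`; default [default_indicator_roles()].
#' @return A list with `table` (counts by species, grade, zone),
#'   `consistency` (named fractions), `n_used`, `n_skipped`.
#' @export
overlay_consistency <- function(records, partition,
                                roles = default_indicator_roles()) {
  stopifnot(all(c("x", "y", "species", "grade") %in% names(records)))
  if (nrow(records) == 0L)
    return(list(table = table(species = character(0), grade = character(0),
                              zone = character(0)),
                consistency = stats::setNames(numeric(0), character(0)),
                n_used = 0L, n_skipped = 0L))
  gm <- partition$geometry
  rc <- point_to_rowcol(gm, records$x, records$y)
  inside <- !is.na(rc[, 1])
  zone <- rep(NA_integer_, nrow(records))
  zone[inside] <- partition$values[cbind(rc[inside, 1], rc[inside, 2])]
  ok <- inside & !is.na(zone) & zone >= 0L
  if (any(!ok))
    warning(sum(!ok), " record(s) outside the extent or on masked pixels; skipped")
  keep <- ok & records$grade != "ungraded"
  zl <- factor(zone[keep], levels = 0:2,
               labels = c("subtropical", "transition", "temperate"))
  tab <- table(species = records$species[keep],
               grade = droplevels(records$grade[keep]), zone = zl)
  cons <- sapply(intersect(names(roles), unique(records$species[keep])),
    function(sp) {
      zsp <- zl[records$species[keep] == sp]
      expected <- if (roles[[sp]] == "subtropical")
        c("subtropical", "transition") else c("temperate", "transition")
      mean(zsp %in% expected)
    })
  list(table = tab, consistency = cons,
       n_used = sum(keep), n_skipped = sum(!ok))
}
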
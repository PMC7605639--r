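#' Fit the full transition-zone model
#'
#' The package's main fitting front-end. Given a covariate stack and the
#' occurrences of one or more indicator-vegetation pairs, it runs the whole
#' workflow in memory: per pair, a q-table over the candidate covariates, an
#' index system (q > `threshold`, top `k`), an SVM two-zone map and its
#' boundary polylines; then the composition of all pairs' boundaries into
#' the transition band, the three-zone partition, and the zonal
#' characterization table.
#'
#' @param stack A [covariate_stack()].
#' @param occurrences List of [veg_occurrence()] objects (one per pair).
#' @param variables Candidate covariate names; default all stack layers.
#' @param threshold,k Index-system selection rule (see
#'   [select_index_system()]).
#' @param B Permutation replicates for q-table p-values (0 skips).
#' @param zoner A [zoner_config()].
#' @param smooth Modal-filter window passed to [predict_zonemap()].
#' @param n_per_zone Zonal sample size for [characterize()].
#' @param seed Master integer seed; per-stage seeds are derived from it.
#' @return An object of class `ecotone_model` with components `qtables`,
#'   `index_systems`, `zoners`, `zonemaps`, `boundaries` (all named by pair
#'   group id), `transition`, `partition`, `zone_table`, `training_accuracy`,
#'   and `call`.
#' @examples
#' \donttest{
#' land <- generate_landscape(synthetic_truth(shape = c(60, 60),
#'                                            occupancy_rate = 0.4))
#' fit <- ecotone_model(land$stack, land$occurrences, B = 0, n_per_zone = 100)
#' print(fit)
#' }
#' @export
ecotone_model <- function(stack, occurrences, variables = names(stack$layers),
                          threshold = 0.3, k = 4, B = 199,
                          zoner = zoner_config(), smooth = 3L,
                          n_per_zone = 500, seed = 1L) {
  assert_aligned(stack)
  if (inherits(occurrences, "veg_occurrence")) occurrences <- list(occurrences)
  if (length(occurrences) < 1L) stop("at least one occurrence set is required")
  ids <- vapply(occurrences, function(o) o$pair$group_id, character(1))
  names(occurrences) <- ids
  seed <- as.integer(seed)
  qtables <- list(); index_systems <- list(); zoners <- list()
  zonemaps <- list(); boundaries <- list(); acc <- numeric(0)
  for (i in seq_along(occurrences)) {
    occ <- occurrences[[i]]
    id <- ids[i]
    qt <- q_table(stack, occ, variables, B = B, seed = seed + 100L * i)
    isys <- select_index_system(qt, threshold = threshold, k = k,
                                pair = occ$pair)
    ex <- extract_labeled_pixels(stack, occ, isys$variables)
    cfg <- zoner; cfg$seed <- seed + 100L * i + 1L
    zn <- fit_zoner(ex$features, ex$labels, cfg)
    acc[id] <- mean(predict(zn, ex$features) == ex$labels)
    zm <- predict_zonemap(zn, stack, isys, smooth = smooth, pair = occ$pair)
    qtables[[id]] <- qt
    index_systems[[id]] <- isys
    zoners[[id]] <- zn
    zonemaps[[id]] <- zm
    boundaries[[id]] <- extract_boundary(zm)
  }
  trans <- compose_transition(boundaries, stack$geometry,
                              mask = Reduce(`|`, lapply(zonemaps, function(z)
                                z$values == -1L)))
  zt <- characterize(trans$partition, stack, variables,
                     n_per_zone = n_per_zone, seed = seed + 7L)
  structure(list(qtables = qtables, index_systems = index_systems,
                 zoners = zoners, zonemaps = zonemaps,
                 boundaries = boundaries, transition = trans,
                 partition = trans$partition, zone_table = zt,
                 training_accuracy = acc, threshold = threshold, k = k,
                 seed = seed, call = match.call()),
            class = "ecotone_model")
}

#' @export
print.ecotone_model <- function(x, ...) {
  cat("Transition-zone model (q-statistic screening + SVM zonation)\n")
  cat(sprintf("  pairs: %s\n", paste(names(x$zonemaps), collapse = ", ")))
  for (id in names(x$index_systems))
    cat(sprintf("  pair %-4s index system: %s (training accuracy %.3f)\n",
                id, format(x$index_systems[[id]]),
                x$training_accuracy[[id]]))
  cat(sprintf("  transition band: mean width %.2f map units\n",
              x$transition$mean_width))
  print(x$partition)
  invisible(x)
}

#' @export
summary.ecotone_model <- function(object, ...) {
  cat("Call: "); print(object$call)
  print(object)
  cat("\nPer-pair q-tables:\n")
  for (id in names(object$qtables)) print(object$qtables[[id]])
  cat("\n")
  print(object$zone_table)
  invisible(object)
}

#' @export
#' @describeIn ecotone_model matrix of q-statistics, variables x pairs.
coef.ecotone_model <- function(object, ...) {
  vars <- object$qtables[[1]]$variable
  sapply(object$qtables, function(qt)
    stats::setNames(qt$q, qt$variable)[vars])
}

#' @export
#' @describeIn ecotone_model re-predict the three-zone partition on a new
#'   covariate stack sharing the selected variables.
predict.ecotone_model <- function(object, newdata = NULL, smooth = 3L, ...) {
  if (is.null(newdata)) return(object$partition)
  zonemaps <- lapply(names(object$zoners), function(id)
    predict_zonemap(object$zoners[[id]], newdata, object$index_systems[[id]],
                    smooth = smooth))
  bounds <- lapply(zonemaps, extract_boundary)
  compose_transition(bounds, newdata$geometry,
                     mask = Reduce(`|`, lapply(zonemaps, function(z)
                       z$values == -1L)))$partition
}

#' @export
plot.ecotone_model <- function(x, ...) {
  p <- x$partition
  gm <- p$geometry
  v <- p$values
  v[v == -1L] <- NA_integer_
  # image() wants x-increasing, y-increasing; flip rows to put north up
  img <- t(v[rev(seq_len(gm$nrow)), , drop = FALSE])
  xs <- gm$origin_x + seq(0, gm$ncol) * gm$cell_size
  ys <- gm$origin_y - seq(gm$nrow, 0) * gm$cell_size
  graphics::image(xs, ys, img, zlim = c(0, 2),
                  col = c("#d95f02", "#f2e28a", "#1b9e77"),
                  xlab = "x", ylab = "y",
                  main = "Three-zone partition (orange S, yellow band, green N)",
                  useRaster = TRUE, ...)
  for (bs in x$boundaries) for (ln in bs$lines)
    graphics::lines(ln[, 1], ln[, 2], col = "grey25", lwd = 0.6)
  invisible(x)
}
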
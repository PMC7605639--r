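#' Random pixel samples within each zone
#'
#' Uniform sampling without replacement inside each of the three zones of a
#' partition (subtropical 0, transition 1, temperate 2). A zone with fewer
#' pixels than `n_per_zone` contributes all of them with a warning; a full
#' census never touches the random number generator, so it is
#' seed-independent.
#'
#' @param partition An `eco_partition` (see [compose_transition()]).
#' @param n_per_zone Samples per zone (default 500).
#' @param seed Integer seed.
#' @return Named list (`subtropical`, `transition`, `temperate`) of
#'   column-major pixel indices into the partition matrix.
#' @export
sample_zones <- function(partition, n_per_zone = 500, seed = 1L) {
  if (n_per_zone < 1) stop("'n_per_zone' must be >= 1")
  v <- partition$values
  zones <- c(subtropical = 0L, transition = 1L, temperate = 2L)
  draw <- function(code, name) {
    idx <- which(v == code)
    if (length(idx) == 0L) stop("empty zone: ", name)
    if (length(idx) <= n_per_zone) {
      if (length(idx) < n_per_zone)
        warning(sprintf("zone '%s' has only %d pixels (requested %d); taking all",
                        name, length(idx), n_per_zone))
      return(idx)
    }
    sort(sample(idx, n_per_zone))
  }
  withr::with_seed(as.integer(seed),
    mapply(draw, zones, names(zones), SIMPLIFY = FALSE))
}

#' Characterize the three zones of a partition
#'
#' For each requested index (covariate), computes the per-zone mean over the
#' sampled pixels and the three-strata q-statistic (strata = subtropical /
#' transition / temperate) on the pooled sample — the quantitative check
#' that the delimited zones really stratify the environment. Values are
#' reported in the raw units of each covariate layer.
#'
#' @param partition An `eco_partition`.
#' @param stack A [covariate_stack()] on the same geometry.
#' @param indexes Covariate names to characterize; default all layers.
#' @param n_per_zone Sample size per zone (see [sample_zones()]).
#' @param seed Integer seed for the zonal sampling.
#' @return A data frame of class `zone_table` with columns `index`, `q`,
#'   `mean_subtropical`, `mean_transition`, `mean_temperate`.
#' @export
characterize <- function(partition, stack, indexes = names(stack$layers),
                         n_per_zone = 500, seed = 1L) {
  missing_v <- setdiff(indexes, names(stack$layers))
  if (length(missing_v))
    stop("indexes not in stack: ", paste(missing_v, collapse = ", "))
  if (!same_geometry(partition$geometry, stack$geometry))
    stop("partition geometry does not match stack")
  smp <- sample_zones(partition, n_per_zone = n_per_zone, seed = seed)
  idx_all <- c(smp$subtropical, smp$transition, smp$temperate)
  h_all <- rep(1:3, times = lengths(smp)[c("subtropical", "transition",
                                           "temperate")])
  res <- data.frame(index = indexes, q = NA_real_,
                    mean_subtropical = NA_real_, mean_transition = NA_real_,
                    mean_temperate = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(indexes)) {
    y <- stack$layers[[indexes[i]]]$values[idx_all]
    ok <- !is.na(y)
    res$q[i] <- factor_q(y[ok], h_all[ok])
    res$mean_subtropical[i] <- mean(y[h_all == 1], na.rm = TRUE)
    res$mean_transition[i] <- mean(y[h_all == 2], na.rm = TRUE)
    res$mean_temperate[i] <- mean(y[h_all == 3], na.rm = TRUE)
  }
  class(res) <- c("zone_table", "data.frame")
  res
}

#' @export
print.zone_table <- function(x, ...) {
  cat("Zone characterization (three-strata q and per-zone means)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
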
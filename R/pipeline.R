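#' Read and validate a run configuration
#'
#' A run configuration is a YAML file (or equivalent list) describing one
#' end-to-end delimitation run: covariate rasters, per-pair occurrence
#' files, the selection rule, classifier settings, sampling sizes, explicit
#' seeds, and the output directory. Validation is performed before any
#' computation; every referenced file must exist and seeds must be explicit
#' (no wall-clock seeding).
#'
#' @param config Path to a YAML file, or a list with the same structure:
#'   \preformatted{
#'   covariates: {meantem01: path.asc, pa: path.asc, ...}
#'   pairs:
#'     - {group_id: II, subtropical: "...", temperate: "...",
#'        occurrences: pairII.geojson}
#'   threshold: 0.3
#'   k: 4
#'   permutations: 199
#'   zoner: {kernel: rbf, C: 1, kernel_scale: auto, standardize: true}
#'   smooth: 3
#'   n_per_zone: 500
#'   seed: 1
#'   quadrats: quadrats.csv     # optional
#'   out_dir: out/
#'   }
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$covariates) || length(cfg$covariates) < 1L)
    stop("config error: 'covariates' must list at least one raster")
  if (is.null(cfg$pairs) || length(cfg$pairs) < 1L)
    stop("config error: 'pairs' must list at least one vegetation pair")
  if (is.null(cfg$seed)) stop("config error: an explicit 'seed' is required")
  if (is.null(cfg$out_dir)) stop("config error: 'out_dir' is required")
  for (nm in names(cfg$covariates))
    if (!file.exists(cfg$covariates[[nm]]))
      stop("config error: covariate file missing: ", cfg$covariates[[nm]])
  for (p in cfg$pairs) {
    for (f in c("group_id", "subtropical", "temperate", "occurrences"))
      if (is.null(p[[f]])) stop("config error: pair entry missing '", f, "'")
    if (!file.exists(p$occurrences))
      stop("config error: occurrence file missing: ", p$occurrences)
  }
  if (!is.null(cfg$quadrats) && !file.exists(cfg$quadrats))
    stop("config error: quadrat file missing: ", cfg$quadrats)
  defaults <- list(threshold = 0.3, k = 4, permutations = 199, smooth = 3,
                   n_per_zone = 500, zoner = list())
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  structure(cfg, class = "run_config")
}

write_csv_stable <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, format = "g", digits = 12))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Run the full delimitation workflow from a configuration
#'
#' Orchestrates the four workflow steps from one config: (1) load and align
#' the covariate stack and rasterize the per-pair occurrences; (2) q-table
#' and index system per pair; (3) SVM zonation and boundary extraction per
#' pair; (4) transition-zone composition, zonal characterization and, if
#' quadrats are supplied, the graded-overlay validation. Every intermediate
#' artifact is written to `out_dir` and logged in the returned manifest;
#' re-running with an identical config reproduces identical text artifacts.
#'
#' @param config A [read_run_config()] result, a config list, or a YAML
#'   path.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest: a list of written artifact paths plus
#'   the parameters and seed, also written as `manifest.json`.
#' @export
run_all <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "preprocess"
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  keep <- function(key, path) artifacts[[key]] <<- path
  res <- tryCatch({
    say("[%s] loading %d covariates", stage, length(cfg$covariates))
    layers <- lapply(cfg$covariates, read_ascii_grid)
    stack <- assert_aligned(covariate_stack(layers))
    occurrences <- list()
    for (p in cfg$pairs) {
      pr <- pair_spec(p$group_id, p$subtropical, p$temperate)
      feats <- read_geojson(p$occurrences)
      occurrences[[pr$group_id]] <- rasterize_occurrences(feats,
                                                          stack$geometry, pr)
    }
    stage <- "model"
    zcfg <- do.call(zoner_config, c(cfg$zoner, list(seed = cfg$seed)))
    fit <- ecotone_model(stack, occurrences,
                         threshold = cfg$threshold, k = cfg$k,
                         B = cfg$permutations, zoner = zcfg,
                         smooth = cfg$smooth, n_per_zone = cfg$n_per_zone,
                         seed = cfg$seed)
    stage <- "write"
    qt_all <- do.call(rbind, lapply(names(fit$qtables), function(id) {
      qt <- fit$qtables[[id]]; qt$pair <- id; qt
    }))
    keep("qtable", write_csv_stable(
      qt_all[, c("pair", "variable", "q", "p_value")],
      file.path(out, "qtable.csv")))
    for (id in names(fit$index_systems)) {
      isys <- fit$index_systems[[id]]
      pth <- file.path(out, sprintf("idx_%s.yaml", id))
      yaml::write_yaml(list(pair = id, threshold = isys$threshold,
                            k = isys$k, short = isys$short,
                            variables = as.list(isys$variables),
                            q = as.list(isys$q)), pth)
      keep(paste0("index_", id), pth)
    }
    for (id in names(fit$zonemaps)) {
      zm <- fit$zonemaps[[id]]
      v <- zm$values; v[v == -1L] <- NA_integer_
      g <- eco_grid(matrix(as.numeric(v), nrow(v), ncol(v)),
                    origin_x = zm$geometry$origin_x,
                    origin_y = zm$geometry$origin_y,
                    cell_size = zm$geometry$cell_size,
                    crs_tag = zm$geometry$crs_tag)
      keep(paste0("zone_", id),
           write_ascii_grid(g, file.path(out, sprintf("zone_%s.asc", id)),
                            nodata = 255))
      keep(paste0("boundaries_", id),
           write_geojson(fit$boundaries[[id]],
                         file.path(out, sprintf("boundaries_%s.geojson", id))))
    }
    keep("transition", write_geojson(fit$transition,
                                     file.path(out, "transition.geojson")))
    keep("zones", write_ascii_grid(partition_grid(fit$partition),
                                   file.path(out, "zones.asc"), nodata = 255))
    keep("width_profile", write_csv_stable(
      data.frame(column = seq_along(fit$transition$width_profile),
                 width = fit$transition$width_profile,
                 interpolated = fit$transition$interpolated),
      file.path(out, "width_profile.csv")))
    keep("zone_table", write_csv_stable(as.data.frame(fit$zone_table),
                                        file.path(out, "zone_table.csv")))
    if (!is.null(cfg$quadrats)) {
      stage <- "validate"
      qd <- utils::read.csv(cfg$quadrats, stringsAsFactors = FALSE)
      graded <- grade_quadrats(qd)
      ov <- overlay_consistency(graded, fit$partition)
      keep("graded_quadrats", write_csv_stable(
        graded, file.path(out, "graded_quadrats.csv")))
      keep("consistency", write_csv_stable(
        data.frame(species = names(ov$consistency),
                   consistency = as.numeric(ov$consistency)),
        file.path(out, "consistency.csv")))
    }
    manifest <- list(
      artifacts = artifacts,
      parameters = list(threshold = cfg$threshold, k = cfg$k,
                        permutations = cfg$permutations,
                        smooth = cfg$smooth, n_per_zone = cfg$n_per_zone,
                        zoner = cfg$zoner, seed = cfg$seed),
      pairs = vapply(cfg$pairs, `[[`, character(1), "group_id"),
      mean_width = fit$transition$mean_width,
      training_accuracy = as.list(fit$training_accuracy))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("[done] %d artifacts in %s", length(artifacts), out)
    manifest
  }, error = function(e)
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
  invisible(res)
}

#' Write a synthetic landscape to disk as pipeline inputs
#'
#' Materializes a [generate_landscape()] result (plus quadrats) into ASCII
#' grids, GeoJSON occurrence points, a quadrat CSV and a truth YAML, and
#' returns a matching run-config list, so the file-based pipeline can be
#' exercised without external data.
#'
#' @param truth A [synthetic_truth()].
#' @param dir Output directory for the fixture files.
#' @param n_quadrats Survey size (default 121).
#' @return A `run_config`-shaped list pointing at the written files.
#' @export
write_synthetic_inputs <- function(truth, dir, n_quadrats = 121) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  land <- generate_landscape(truth)
  cov <- list()
  for (nm in names(land$stack$layers)) {
    pth <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(land$stack$layers[[nm]], pth)
    cov[[nm]] <- pth
  }
  gm <- land$stack$geometry
  pairs <- list()
  for (id in names(land$occurrences)) {
    occ <- land$occurrences[[id]]
    pos <- which(occ$labels >= 0L)
    r <- (pos - 1L) %% gm$nrow + 1L
    c <- (pos - 1L) %/% gm$nrow + 1L
    df <- data.frame(x = pixel_center_x(gm, c), y = pixel_center_y(gm, r),
                     veg_type = ifelse(occ$labels[pos] == 0L,
                                       occ$pair$subtropical_name,
                                       occ$pair$temperate_name))
    pth <- file.path(dir, sprintf("occurrences_%s.geojson", id))
    write_geojson(df, pth)
    pairs[[length(pairs) + 1L]] <- list(
      group_id = id, subtropical = occ$pair$subtropical_name,
      temperate = occ$pair$temperate_name, occurrences = pth)
  }
  qd <- generate_quadrats(truth, n_quadrats = n_quadrats)
  qpth <- file.path(dir, "quadrats.csv")
  utils::write.csv(qd, qpth, row.names = FALSE)
  ypth <- file.path(dir, "truth.yaml")
  brows <- if (all(vapply(truth$boundary_rows, is.numeric, logical(1))))
    as.list(unlist(truth$boundary_rows)) else "functional"
  yaml::write_yaml(list(shape = as.list(truth$shape),
                        boundary_rows = brows,
                        drivers = as.list(truth$drivers),
                        nuisances = as.list(truth$nuisances),
                        noise_sd = truth$noise_sd,
                        occupancy_rate = truth$occupancy_rate,
                        seed = truth$seed), ypth)
  list(covariates = cov, pairs = pairs, quadrats = qpth, seed = truth$seed,
       out_dir = file.path(dir, "out"))
}
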
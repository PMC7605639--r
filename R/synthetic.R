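#' Ground-truth configuration of a synthetic landscape
#'
#' Bundles the generating parameters of a simulated study area: a north-up
#' grid crossed by a latitudinal climate turnover, one indicator-vegetation
#' pair per boundary, driver covariates that respond logistically to the
#' turnover, spatially autocorrelated nuisance covariates (emulating weak
#' soil factors), sparse vegetation observation, and a survey model for
#' quadrat counts. The defaults are the package's reference study
#' conditions: a 200 x 200 grid (1-km cells), three pairs with flat true
#' boundaries 15 cells apart at rows 85 / 100 / 115, driver noise at 0.3 of
#' the gradient range, and 15 % observation (occupancy) of each class.
#'
#' @param shape `c(nrow, ncol)` of the grid; at least 50 x 50 for recovery
#'   work.
#' @param pairs List of [pair_spec()]s, one per boundary.
#' @param boundary_rows Per pair, the true boundary: a single number (flat
#'   boundary at that row edge, counted from the north) or a function of the
#'   column index returning the row. Rows 1..b are temperate, the rest
#'   subtropical.
#' @param drivers Names of the driver covariates. Driver k turns over at the
#'   boundary of pair `((k-1) %% n_pairs) + 1`, so every pair has a matched
#'   steep driver — different vegetation pairs respond to different climate
#'   variables with different thresholds.
#' @param nuisances Names of the label-independent nuisance covariates.
#' @param gradient_range Covariate units spanned by each driver's turnover
#'   (default 10).
#' @param turnover_width Cells over which a driver's logistic response turns
#'   over (its scale parameter; default 1, i.e. the vegetation-relevant
#'   climatic threshold is quasi-categorical at the grid resolution — see
#'   the methods vignette for the identifiability argument).
#' @param noise_sd Gaussian noise sd on drivers, covariate units; default
#'   `0.3 * gradient_range`.
#' @param nuisance_sd,nuisance_scale Amplitude (sd) and autocorrelation
#'   length (cells) of the smoothed nuisance fields.
#' @param include_dem Also generate a `dem` layer: linear north-south slope
#'   plus an east-west ridge bump plus noise (default `TRUE`).
#' @param occupancy_rate Probability that a pixel of a pair's class is
#'   actually observed (labeled); the rest stay -1, mimicking vegetation
#'   polygons that cover only part of each climate zone.
#' @param quadrat_decay Per-cell logistic decay rate of quadrat count means
#'   past a species' boundary.
#' @param lam_max Plateau Poisson means for quadrat counts,
#'   `c(subtropical =, temperate =)`.
#' @param seed Integer master seed.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(shape = c(200L, 200L),
                            pairs = list(
                              pair_spec("I", "Quercus fabri forest",
                                        "Quercus wutaishanica forest"),
                              pair_spec("II", "Pinus massoniana forest",
                                        "Pinus tabuliformis forest"),
                              pair_spec("III", "Cyclobalanopsis glauca forest",
                                        "Populus davidiana forest")),
                            boundary_rows = NULL,
                            drivers = c("meantem01", "pa", "tadem"),
                            nuisances = c("sand_content", "silt_content",
                                          "soil_organic"),
                            gradient_range = 10,
                            turnover_width = 1,
                            noise_sd = 0.3 * gradient_range,
                            nuisance_sd = 1.5, nuisance_scale = 8,
                            include_dem = TRUE,
                            occupancy_rate = 0.15,
                            quadrat_decay = 0.25,
                            lam_max = c(subtropical = 30, temperate = 25),
                            seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 2L)) stop("degenerate shape")
  np <- length(pairs)
  if (np < 1L) stop("at least one pair is required")
  if (is.null(boundary_rows)) {
    # flat boundaries 15 cells apart, centred on the grid
    offs <- if (np == 1L) 0 else seq(-7.5 * (np - 1), 7.5 * (np - 1),
                                     length.out = np)
    boundary_rows <- round(shape[1] / 2 + offs)
  }
  if (length(boundary_rows) != np)
    stop("'boundary_rows' must have one entry per pair")
  bfn <- lapply(boundary_rows, function(b)
    if (is.function(b)) b else local({bb <- b; function(col) rep(bb, length(col))}))
  brow <- vapply(seq_len(shape[2]), function(j)
    vapply(bfn, function(f) f(j)[1], numeric(1)), numeric(np))
  if (np == 1L) brow <- matrix(brow, nrow = 1L)
  if (any(brow < 1) || any(brow > shape[1] - 1))
    stop("boundary rows must lie inside the grid")
  if (occupancy_rate < 0 || occupancy_rate > 1)
    stop("'occupancy_rate' must be in [0, 1]")
  # rate 0 is allowed: it yields all-absent labels, which downstream
  # extraction rejects as an unusable pair
  structure(list(shape = shape, pairs = pairs, boundary_row_fn = bfn,
                 boundary_rows = boundary_rows,
                 drivers = drivers, nuisances = nuisances,
                 gradient_range = gradient_range,
                 turnover_width = turnover_width, noise_sd = noise_sd,
                 nuisance_sd = nuisance_sd, nuisance_scale = nuisance_scale,
                 include_dem = isTRUE(include_dem),
                 occupancy_rate = occupancy_rate,
                 quadrat_decay = quadrat_decay, lam_max = lam_max,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

# spatially autocorrelated Gaussian field: white noise smoothed with a
# circular moving average of width ~scale in both directions, rescaled to sd
smooth_field <- function(nr, nc, sd, scale) {
  w <- max(3L, 2L * as.integer(scale) %/% 2L + 1L)
  k <- rep(1 / w, w)
  m <- matrix(stats::rnorm(nr * nc), nr, nc)
  m <- stats::filter(m, k, circular = TRUE)               # down columns
  m <- t(stats::filter(t(m), k, circular = TRUE))         # along rows
  m <- as.matrix(m)
  m <- (m - mean(m)) / stats::sd(m) * sd
  m
}

#' Generate a synthetic landscape with known truth
#'
#' Realizes the configuration of [synthetic_truth()] into a covariate stack
#' and per-pair vegetation occurrences. Driver covariates rise monotonically
#' from north to south through a logistic turnover of `gradient_range` units
#' centred on their matched pair's boundary, plus white Gaussian noise;
#' nuisance covariates are spatially autocorrelated noise independent of the
#' labels; the optional `dem` layer adds a linear slope and an east-west
#' ridge. Each pixel's true class is set by its position relative to the
#' pair's boundary curve (temperate north of it), and is observed with
#' probability `occupancy_rate`. Everything is reproducible from the truth
#' seed.
#'
#' @param truth A [synthetic_truth()].
#' @return A list with `stack` ([covariate_stack()]), `occurrences` (named
#'   list of [veg_occurrence()], one per pair), and `truth` (the input,
#'   echoed).
#' @export
generate_landscape <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  nr <- truth$shape[1]; nc <- truth$shape[2]
  if (nr < 2L || nc < 2L) stop("degenerate shape")
  np <- length(truth$pairs)
  withr::with_seed(truth$seed, {
    rowc <- matrix(seq_len(nr) - 0.5, nr, nc)          # row centers, edge coords
    bmat <- vapply(seq_len(np), function(p)
      vapply(seq_len(nc), function(j) truth$boundary_row_fn[[p]](j)[1],
             numeric(1)), numeric(nc))                  # nc x np
    layers <- list()
    for (k in seq_along(truth$drivers)) {
      p <- (k - 1L) %% np + 1L
      mid <- matrix(rep(bmat[, p], each = nr), nr, nc)
      a <- 1 + 0.1 * ((k - 1) %% 3 - 1)                # mild per-driver scale
      vals <- a * truth$gradient_range *
        stats::plogis((rowc - mid) / truth$turnover_width) +
        stats::rnorm(nr * nc, sd = truth$noise_sd)
      layers[[truth$drivers[k]]] <- eco_grid(vals, crs_tag = "synthetic")
    }
    for (nm in truth$nuisances)
      layers[[nm]] <- eco_grid(
        smooth_field(nr, nc, truth$nuisance_sd, truth$nuisance_scale) +
          truth$nuisance_sd * 2,                       # positive-ish soil units
        crs_tag = "synthetic")
    if (truth$include_dem) {
      colc <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
      ridge <- 800 * exp(-((rowc - 0.35 * nr) / (0.1 * nr))^2)
      vals <- 1500 - 3 * (rowc - nr / 2) + ridge +
        30 * sin(2 * pi * colc / nc) +
        stats::rnorm(nr * nc, sd = 40)
      layers[["dem"]] <- eco_grid(vals, crs_tag = "synthetic")
    }
    stack <- covariate_stack(layers)
    occurrences <- list()
    for (p in seq_len(np)) {
      bm <- matrix(rep(bmat[, p], each = nr), nr, nc)
      cls <- ifelse(rowc < bm, 1L, 0L)                 # temperate north
      obs <- matrix(stats::runif(nr * nc) < truth$occupancy_rate, nr, nc)
      lab <- ifelse(obs, cls, -1L)
      occurrences[[truth$pairs[[p]]$group_id]] <-
        veg_occurrence(lab, truth$pairs[[p]], stack$geometry)
    }
    list(stack = stack, occurrences = occurrences, truth = truth)
  })
}

#' Generate synthetic quadrat survey records
#'
#' Simulates a field survey: quadrat locations uniform over the grid, and a
#' stem count per record drawn from a Poisson whose mean sits at the
#' species' plateau south (for subtropical indicators) or north (temperate)
#' of its true boundary and decays logistically past it at
#' `quadrat_decay` per cell. Species are the three default indicator
#' species; each is tied to the boundary of the pair whose member it is
#' (Platycarya strobilacea, unpaired, follows the first pair's boundary).
#'
#' @param truth A [synthetic_truth()].
#' @param n_quadrats Number of records (default 121, a realistic survey
#'   size).
#' @param seed Integer seed; default derives from the truth seed.
#' @return Data frame with columns `x`, `y`, `species`, `count`.
#' @export
generate_quadrats <- function(truth, n_quadrats = 121, seed = truth$seed + 1000L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (n_quadrats < 1) stop("'n_quadrats' must be >= 1")
  nr <- truth$shape[1]; nc <- truth$shape[2]
  roles <- default_indicator_roles()
  species <- names(roles)
  pair_of_species <- function(sp) {
    for (p in seq_along(truth$pairs)) {
      pr <- truth$pairs[[p]]
      if (grepl(sp, pr$subtropical_name, fixed = TRUE) ||
          grepl(sp, pr$temperate_name, fixed = TRUE)) return(p)
    }
    1L
  }
  withr::with_seed(as.integer(seed), {
    x <- stats::runif(n_quadrats, 0, nc)
    y <- stats::runif(n_quadrats, 0, nr)
    sp <- species[(seq_len(n_quadrats) - 1L) %% length(species) + 1L]
    count <- integer(n_quadrats)
    for (i in seq_len(n_quadrats)) {
      p <- pair_of_species(sp[i])
      col <- min(max(ceiling(x[i]), 1L), nc)
      b <- truth$boundary_row_fn[[p]](col)[1]
      r <- nr - y[i]                                  # fractional row from north
      d <- if (roles[[sp[i]]] == "subtropical") r - b else b - r
      lam <- truth$lam_max[[roles[[sp[i]]]]] *
        stats::plogis(truth$quadrat_decay * d)
      count[i] <- stats::rpois(1, lam)
    }
    data.frame(x = x, y = y, species = sp, count = count,
               stringsAsFactors = FALSE)
  })
}
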
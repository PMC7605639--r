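#' Configuration of the max-margin zonation classifier
#'
#' Hyperparameters of the binary support vector machine used to turn labeled
#' training pixels into a wall-to-wall two-zone map. The boundary position is
#' sensitive to these, which is why they are all exposed.
#'
#' @param kernel `"rbf"` (Gaussian radial basis, default) or `"linear"`.
#' @param C Positive regularization (soft-margin cost), default 1.
#' @param kernel_scale RBF inverse-width gamma; `"auto"` (default) uses
#'   `1 / (n_features * var(features))` computed on the standardized
#'   training matrix.
#' @param standardize Z-score each feature with training mean/sd before
#'   fitting (default `TRUE`); the parameters are stored with the predictor
#'   and re-applied at prediction time.
#' @param class_weights Inverse-frequency class weighting (default `TRUE`),
#'   guarding against the usually unequal pixel counts of the two
#'   vegetation types.
#' @param seed Integer seed fixed before fitting.
#' @return A list of class `zoner_config`.
#' @export
zoner_config <- function(kernel = c("rbf", "linear"), C = 1,
                         kernel_scale = "auto", standardize = TRUE,
                         class_weights = TRUE, seed = 1L) {
  kernel <- match.arg(kernel)
  if (!is.numeric(C) || C <= 0) stop("'C' must be positive")
  structure(list(kernel = kernel, C = C, kernel_scale = kernel_scale,
                 standardize = isTRUE(standardize),
                 class_weights = isTRUE(class_weights),
                 seed = as.integer(seed)),
            class = "zoner_config")
}

#' Fit the two-zone max-margin classifier
#'
#' Trains a binary SVM on labeled pixels' selected covariates. Features are
#' optionally z-scored (parameters stored), classes may be inverse-frequency
#' weighted, and training is deterministic given the configuration seed.
#'
#' @param features Numeric matrix, one row per training pixel, one column
#'   per selected covariate (see [extract_labeled_pixels()]).
#' @param labels Integer vector in \{0, 1\} (0 = subtropical, 1 = temperate);
#'   both classes must be present.
#' @param cfg A [zoner_config()].
#' @return An object of class `eco_zoner` wrapping the fitted model plus the
#'   standardization parameters and feature names.
#' @seealso [predict_zonemap()]
#' @export
fit_zoner <- function(features, labels, cfg = zoner_config()) {
  features <- as.matrix(features)
  if (any(!is.finite(features))) stop("non-finite feature values")
  labels <- as.integer(labels)
  if (length(labels) != nrow(features))
    stop("'labels' length must match feature rows")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in 'labels'")
  if (is.null(colnames(features)))
    colnames(features) <- paste0("V", seq_len(ncol(features)))
  center <- rep(0, ncol(features)); scale <- rep(1, ncol(features))
  if (cfg$standardize) {
    center <- colMeans(features)
    scale <- apply(features, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  Xs <- sweep(sweep(features, 2, center), 2, scale, "/")
  gamma <- if (identical(cfg$kernel_scale, "auto")) {
    v <- stats::var(as.vector(Xs))
    if (!is.finite(v) || v == 0) 1 else 1 / (ncol(Xs) * v)
  } else as.numeric(cfg$kernel_scale)
  wts <- NULL
  if (cfg$class_weights) {
    n <- length(labels)
    wts <- c("0" = n / (2 * sum(labels == 0L)),
             "1" = n / (2 * sum(labels == 1L)))
  }
  yf <- factor(labels, levels = c(0L, 1L))
  model <- withr::with_seed(cfg$seed,
    e1071::svm(x = Xs, y = yf,
               kernel = if (cfg$kernel == "rbf") "radial" else "linear",
               cost = cfg$C, gamma = gamma, scale = FALSE,
               class.weights = wts, probability = FALSE))
  structure(list(model = model, center = center, scale = scale,
                 gamma = gamma, variables = colnames(features), cfg = cfg),
            class = "eco_zoner")
}

#' @export
print.eco_zoner <- function(x, ...) {
  cat(sprintf("<eco_zoner> %s kernel, C = %g, gamma = %.4g, %d SVs, vars: %s\n",
              x$cfg$kernel, x$cfg$C, x$gamma, x$model$tot.nSV,
              paste(x$variables, collapse = ", ")))
  invisible(x)
}

#' @export
predict.eco_zoner <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$variables))
    stop("newdata must have ", length(object$variables), " columns")
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  as.integer(as.character(stats::predict(object$model, Xs)))
}

# 3x3 (or wxw) modal filter on a {-1,0,1} map; -1 cells are left untouched
# and never vote. Standard post-classification cleanup of per-pixel speckle.
modal_filter <- function(z, window = 3L) {
  if (window < 2L) return(z)
  nr <- nrow(z); nc <- ncol(z)
  half <- (window - 1L) %/% 2L
  offs <- -half:half
  ones <- matrix(0, nr, nc); zeros <- matrix(0, nr, nc)
  is1 <- (z == 1L); is0 <- (z == 0L)
  for (dr in offs) for (dc in offs) {
    rs <- pmin(pmax(seq_len(nr) + dr, 1L), nr)   # replicate-pad edges
    cs <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    ones <- ones + is1[rs, cs]
    zeros <- zeros + is0[rs, cs]
  }
  out <- z
  live <- z >= 0L
  out[live & (ones > zeros)] <- 1L
  out[live & (zeros > ones)] <- 0L
  out                                            # ties keep original value
}

#' Predict a wall-to-wall two-zone map
#'
#' Classifies every pixel of the stack whose selected covariates are all
#' non-masked; masked pixels propagate as -1. Prediction streams in row
#' blocks (an implementation constant with no effect on output). A modal
#' (majority) filter of width `smooth` is applied to the classified map as
#' standard post-classification cleanup; `smooth = 0` or `1` disables it.
#'
#' @param zoner A fitted [fit_zoner()] predictor.
#' @param stack A [covariate_stack()] containing all index-system variables.
#' @param index_system An [select_index_system()] result or a character
#'   vector of variable names, in the order the zoner was trained on.
#' @param smooth Modal filter window in pixels (odd; default 3).
#' @param pair Optional [pair_spec()] recorded on the map.
#' @return An object of class `eco_zonemap`: integer matrix `values` in
#'   \{-1 masked, 0 subtropical, 1 temperate\} plus `geometry`, `pair`,
#'   `index_system`.
#' @export
predict_zonemap <- function(zoner, stack, index_system, smooth = 3L,
                            pair = NULL) {
  vars <- if (inherits(index_system, "index_system")) index_system$variables
          else as.character(index_system)
  missing_v <- setdiff(vars, names(stack$layers))
  if (length(missing_v))
    stop("stack is missing index-system variable(s): ",
         paste(missing_v, collapse = ", "))
  if (!identical(vars, zoner$variables))
    stop("index system does not match the variables the zoner was trained on")
  gm <- stack$geometry
  n <- gm$nrow * gm$ncol
  X <- vapply(zoner$variables, function(v) as.vector(stack$layers[[v]]$values),
              numeric(n))
  ok <- rowSums(is.na(X)) == 0L
  zvec <- rep(-1L, n)
  if (any(ok)) {
    idx <- which(ok)
    block <- 50000L
    for (s in seq(1L, length(idx), by = block)) {
      ii <- idx[s:min(s + block - 1L, length(idx))]
      zvec[ii] <- predict(zoner, X[ii, , drop = FALSE])
    }
  }
  z <- matrix(zvec, gm$nrow, gm$ncol)
  z <- modal_filter(z, as.integer(smooth))
  if (is.null(pair) && inherits(index_system, "index_system"))
    pair <- index_system$pair
  structure(list(values = z, geometry = gm, pair = pair,
                 index_system = if (inherits(index_system, "index_system"))
                   index_system else NULL),
            class = "eco_zonemap")
}

#' @export
print.eco_zonemap <- function(x, ...) {
  tb <- table(factor(x$values, levels = c(-1, 0, 1)))
  cat(sprintf("<eco_zonemap%s> masked %d | subtropical %d | temperate %d\n",
              if (!is.null(x$pair)) paste0(" pair ", x$pair$group_id) else "",
              tb[["-1"]], tb[["0"]], tb[["1"]]))
  invisible(x)
}
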
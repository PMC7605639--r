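#' Factor-detector q-statistic
#'
#' Variance-decomposition measure of spatial stratified heterogeneity:
#' \deqn{q = 1 - \frac{\sum_{h=1}^{L} N_h \sigma_h^2}{N \sigma^2}}
#' with population (divide-by-N) variances, so q reduces exactly to
#' 1 - SSW/SST, the one-way ANOVA eta-squared. q = 0 means the strata explain
#' none of the variance of `y`; q = 1 means every stratum is internally
#' constant. A constant `y` (SST = 0) returns 0: there is no variance to
#' explain. Tiny negative rounding is clamped to 0.
#'
#' @param y Numeric vector of the attribute (here: a covariate sampled at
#'   labeled pixels).
#' @param h Stratum labels (any atomic type; at least 2 distinct values,
#'   every stratum non-empty by construction).
#' @return The q-statistic, a dimensionless value in \[0, 1\].
#' @examples
#' factor_q(c(1, 2, 3, 7, 8, 9), c(1, 1, 1, 2, 2, 2))
#' @export
factor_q <- function(y, h) {
  if (length(y) != length(h)) stop("'y' and 'h' must have equal length")
  if (any(!is.finite(y))) stop("non-finite values in 'y'")
  hi <- as.integer(factor(h))
  L <- max(hi)
  if (L < 2L) stop("insufficient strata: q requires at least 2 strata")
  N <- length(y)
  if (N < L) stop("fewer samples than strata")
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) return(0)
  gm <- vapply(split(y, hi), mean, numeric(1))
  ssw <- sum((y - gm[hi])^2)
  min(max(1 - ssw / sst, 0), 1)
}

#' Permutation significance test for the q-statistic
#'
#' Monte-Carlo permutation test of the null that the stratification carries
#' no information about `y`: the stratum labels are permuted uniformly B
#' times and \eqn{p = (1 + \#\{q_b \ge q_{obs}\}) / (B + 1)}. The comparison
#' uses a 1e-12 slack so floating-point ties count as ties.
#'
#' @inheritParams factor_q
#' @param B Number of permutation replicates (at least 99).
#' @param seed Integer seed making the test reproducible; `NULL` uses the
#'   current RNG state.
#' @return The permutation p-value in (0, 1\].
#' @export
permutation_p <- function(y, h, B = 999, seed = NULL) {
  if (!is.numeric(B) || length(B) != 1L || B < 99)
    stop("'B' must be a single number >= 99")
  B <- as.integer(B)
  q_obs <- factor_q(y, h)
  run <- function() {
    ge <- 0L
    for (b in seq_len(B))
      if (factor_q(y, sample(h)) >= q_obs - 1e-12) ge <- ge + 1L
    (1 + ge) / (B + 1)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Per-pair q-table over candidate covariates
#'
#' For one vegetation pair, computes the q-statistic (and optionally a
#' permutation p-value) of every candidate covariate, using the two
#' vegetation classes as the strata: for each variable the sample is the
#' covariate value at every labeled (0/1), non-masked pixel and the strata
#' are the labels.
#'
#' @param stack A [covariate_stack()].
#' @param occ A [veg_occurrence()] for the pair.
#' @param variables Candidate covariate names; default all stack layers.
#' @param B Permutation replicates for the significance test; `0` skips the
#'   test (p-values `NA`).
#' @param seed Integer seed for the permutation test.
#' @return A data frame of class `qtable` with columns `variable`, `q`,
#'   `p_value`, ordered as `variables`.
#' @export
q_table <- function(stack, occ, variables = names(stack$layers),
                    B = 199, seed = 1L) {
  if (length(variables) < 1L) stop("'variables' must be nonempty")
  res <- data.frame(variable = variables, q = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(variables)) {
    ex <- extract_labeled_pixels(stack, occ, variables[i])
    y <- ex$features[, 1]
    hlab <- ex$labels + 1L
    res$q[i] <- factor_q(y, hlab)
    if (B >= 99)
      res$p_value[i] <- permutation_p(y, hlab, B = B,
                                      seed = as.integer(seed) + i)
  }
  class(res) <- c("qtable", "data.frame")
  attr(res, "pair") <- occ$pair
  res
}

#' @export
print.qtable <- function(x, ...) {
  pr <- attr(x, "pair")
  if (!is.null(pr)) cat(sprintf("q-table for pair %s\n", pr$group_id))
  print.data.frame(x[order(-x$q), ], row.names = FALSE, digits = 4)
  invisible(x)
}
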
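test_that("factor_q matches hand-worked decompositions", {
  # zero within-stratum variance explains everything
  expect_equal(factor_q(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # equal stratum means explain nothing
  expect_equal(factor_q(c(1, 2, 1, 2), c(1, 1, 2, 2)), 0)
  # SST = 58, SSW = 2 + 2 by explicit sums
  expect_equal(factor_q(c(1, 2, 3, 7, 8, 9), c(1, 1, 1, 2, 2, 2)),
               1 - 4 / 58, tolerance = 1e-15)
})

test_that("factor_q equals the brute-force eta-squared oracle", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(4:50, 1)
    L <- sample(2:4, 1)
    h <- c(seq_len(L), sample(seq_len(L), n - L, replace = TRUE))
    y <- rnorm(n)
    expect_lt(abs(factor_q(y, h) - oracle_eta2(y, h)), 1e-12)
  }
})

test_that("factor_q agrees with an ANOVA fit on a non-trivial sample", {
  set.seed(7)
  y <- rnorm(40) + rep(c(0, 1.5, 3), length.out = 40)
  h <- rep(1:4, each = 10)
  a <- anova(lm(y ~ factor(h)))
  eta2 <- a$`Sum Sq`[1] / sum(a$`Sum Sq`)
  expect_equal(factor_q(y, h), eta2, tolerance = 1e-12)
})

test_that("q is affine-invariant, bounded, and degenerates gracefully", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    y <- rnorm(n)
    h <- sample(1:3, n, replace = TRUE)
    if (length(unique(h)) < 2) next
    q0 <- factor_q(y, h)
    expect_gte(q0, 0); expect_lte(q0, 1)
    for (a in c(-2, 0.001, 1e6))
      expect_lt(abs(factor_q(a * y + 5, h) - q0), 1e-12)
  }
  # constant y: nothing to explain
  expect_equal(factor_q(rep(3, 10), rep(1:2, 5)), 0)
  # q = 1 iff every stratum internally constant (given SST > 0)
  expect_equal(factor_q(c(5, 5, 9, 9, 9), c(1, 1, 2, 2, 2)), 1)
  expect_lt(factor_q(c(5, 5.1, 9, 9, 9), c(1, 1, 2, 2, 2)), 1)

  expect_error(factor_q(1:5, rep(1, 5)), "insufficient strata")
  expect_error(factor_q(c(1, NA, 3, 4), c(1, 1, 2, 2)), "non-finite")
  expect_error(factor_q(c(1, Inf, 3, 4), c(1, 1, 2, 2)), "non-finite")
})

test_that("permutation p matches the exhaustive enumeration oracle", {
  y <- c(0, 0, 0, 10, 10, 10)
  h <- c(1, 1, 1, 2, 2, 2)
  q_obs <- factor_q(y, h)
  # all C(6,3) = 20 balanced arrangements, each equally likely under
  # uniform permutation of h
  combs <- utils::combn(6, 3)
  qs <- apply(combs, 2, function(ix) {
    hh <- rep(2, 6); hh[ix] <- 1
    factor_q(y, hh)
  })
  p_exact <- mean(qs >= q_obs - 1e-12)
  expect_equal(p_exact, 0.1)                # 2 of 20 perfect splits
  p_mc <- permutation_p(y, h, B = 9999, seed = 4)
  se <- sqrt(p_exact * (1 - p_exact) / 9999)
  expect_lt(abs(p_mc - p_exact), 3 * se + 1 / 10000)
})

test_that("permutation p is reproducible, valid and super-uniform under the null", {
  y <- rnorm(30); h <- rep(1:2, 15)
  expect_identical(permutation_p(y, h, B = 199, seed = 9),
                   permutation_p(y, h, B = 199, seed = 9))
  expect_error(permutation_p(y, h, B = 50), ">= 99")
  expect_error(permutation_p(y, rep(1, 30), B = 199), "insufficient strata")

  # type-I error at alpha = 0.05 across independent null datasets
  set.seed(2024)
  rej <- replicate(400, {
    yy <- rnorm(100)
    hh <- sample(rep(1:2, 50))
    permutation_p(yy, hh, B = 99) <= 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("q_table screens covariates with labels as strata", {
  land <- small_landscape(seed = 3, shape = c(50, 50), pairs = 1)
  st <- land$stack
  occ <- land$occurrences[[1]]
  # add a constant layer and an exact label-indicator layer
  const <- eco_grid(matrix(5, 50, 50), crs_tag = "synthetic")
  ind <- eco_grid(matrix(as.numeric(occ$labels == 1L), 50, 50),
                  crs_tag = "synthetic")
  st2 <- covariate_stack(c(st$layers, list(const = const, indicator = ind)))
  qt <- q_table(st2, occ, B = 0)
  expect_equal(qt$q[qt$variable == "const"], 0)
  expect_equal(qt$q[qt$variable == "indicator"], 1)
  # the drivers out-rank the nuisances on generated truth
  expect_gt(min(qt$q[qt$variable %in% land$truth$drivers]),
            max(qt$q[qt$variable %in% land$truth$nuisances]))
  # p-values computed and reproducible when requested
  qt2 <- q_table(st2, occ, variables = "meantem01", B = 99, seed = 5)
  qt3 <- q_table(st2, occ, variables = "meantem01", B = 99, seed = 5)
  expect_equal(qt2$p_value, qt3$p_value)
  expect_lte(qt2$p_value, 0.05)
})
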
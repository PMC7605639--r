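test_that("a separable 1-D problem is refit perfectly and errors are caught", {
  X <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1,
              dimnames = list(NULL, "grad"))
  y <- c(0L, 0L, 0L, 1L, 1L, 1L)
  zn <- fit_zoner(X, y)
  expect_identical(predict(zn, X), y)

  expect_error(fit_zoner(X, rep(0L, 6)), "both classes")
  X2 <- X; X2[3] <- NA
  expect_error(fit_zoner(X2, y), "non-finite")
  expect_error(fit_zoner(X, y[-1]), "length")
})

test_that("training on a noisy synthetic landscape is accurate", {
  land <- small_landscape(seed = 11, shape = c(100, 100), pairs = 1,
                          occupancy = 0.5)
  occ <- land$occurrences[[1]]
  ex <- extract_labeled_pixels(land$stack, occ, land$truth$drivers)
  expect_gt(nrow(ex$features), 4000)
  zn <- fit_zoner(ex$features, ex$labels, zoner_config(seed = 3))
  acc <- mean(predict(zn, ex$features) == ex$labels)
  expect_gte(acc, 0.95)
})

test_that("unit changes and training-row order do not move the zone map", {
  land <- small_landscape(seed = 5, shape = c(40, 40), pairs = 1,
                          occupancy = 0.6)
  occ <- land$occurrences[[1]]
  vars <- land$truth$drivers
  ex <- extract_labeled_pixels(land$stack, occ, vars)
  cfg <- zoner_config(seed = 2)

  zn <- fit_zoner(ex$features, ex$labels, cfg)
  zm <- predict_zonemap(zn, land$stack, vars, smooth = 0)

  # multiply one covariate by 1000 everywhere (a unit change)
  st2 <- land$stack
  st2$layers[[vars[1]]]$values <- st2$layers[[vars[1]]]$values * 1000
  ex2 <- extract_labeled_pixels(st2, occ, vars)
  zn2 <- fit_zoner(ex2$features, ex2$labels, cfg)
  zm2 <- predict_zonemap(zn2, st2, vars, smooth = 0)
  expect_equal(zm2$values, zm$values)

  # permute training rows
  set.seed(99)
  perm <- sample(nrow(ex$features))
  zn3 <- fit_zoner(ex$features[perm, ], ex$labels[perm], cfg)
  zm3 <- predict_zonemap(zn3, land$stack, vars, smooth = 0)
  expect_equal(zm3$values, zm$values)
})

test_that("zone maps partition non-masked pixels and propagate masks", {
  land <- small_landscape(seed = 8, shape = c(40, 40), pairs = 1,
                          occupancy = 0.6)
  occ <- land$occurrences[[1]]
  vars <- land$truth$drivers
  st <- land$stack
  st$layers[[vars[1]]]$values[1:5, 1:10] <- NA     # mask a corner
  ex <- extract_labeled_pixels(st, occ, vars)
  zn <- fit_zoner(ex$features, ex$labels)
  zm <- predict_zonemap(zn, st, vars)
  expect_true(all(zm$values[1:5, 1:10] == -1L))
  expect_equal(sum(zm$values == 0L) + sum(zm$values == 1L),
               sum(!is.na(st$layers[[vars[1]]]$values)))

  # fully masked stack predicts a fully masked map
  st_all <- st
  for (v in vars) st_all$layers[[v]]$values[] <- NA
  zm_all <- predict_zonemap(zn, st_all, vars)
  expect_true(all(zm_all$values == -1L))

  expect_error(predict_zonemap(zn, st, c(vars, "nope")), "missing")
  expect_error(predict_zonemap(zn, st, vars[-1]), "does not match")
})

test_that("the recovered boundary sits at the generating row", {
  land <- small_landscape(seed = 21, shape = c(80, 80), pairs = 1,
                          occupancy = 0.3)
  occ <- land$occurrences[[1]]
  vars <- land$truth$drivers
  ex <- extract_labeled_pixels(land$stack, occ, vars)
  zn <- fit_zoner(ex$features, ex$labels, zoner_config(seed = 1))
  zm <- predict_zonemap(zn, land$stack, vars)
  b <- land$truth$boundary_rows[[1]]
  # away from the boundary the generating class must be recovered
  far_n <- zm$values[seq_len(b - 5), ]
  far_s <- zm$values[(b + 6):80, ]
  expect_gte(mean(far_n == 1L), 0.95)
  expect_gte(mean(far_s == 0L), 0.95)
})

test_that("an independent max-margin implementation agrees", {
  land <- small_landscape(seed = 4, shape = c(40, 40), pairs = 1,
                          occupancy = 0.5)
  occ <- land$occurrences[[1]]
  ex <- extract_labeled_pixels(land$stack, occ, land$truth$drivers)
  zn <- fit_zoner(ex$features, ex$labels, zoner_config(seed = 1))
  ours <- predict(zn, ex$features)
  km <- kernlab::ksvm(x = scale(ex$features), y = factor(ex$labels),
                      kernel = "rbfdot",
                      kpar = list(sigma = zn$gamma), C = 1, scaled = FALSE)
  theirs <- as.integer(as.character(kernlab::predict(km, scale(ex$features))))
  expect_gt(mean(ours == theirs), 0.98)
})
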
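band_fixture <- function(nr = 50, nc = 40, rows = c(10, 40)) {
  bsets <- lapply(rows, function(b) extract_boundary(horizontal_zonemap(nr, nc, b)))
  list(bsets = bsets, gm = eco_grid(matrix(0, nr, nc))$geometry)
}

test_that("two horizontal boundaries span the band between them", {
  fx <- band_fixture(rows = c(10, 40))
  tz <- compose_transition(fx$bsets, fx$gm)
  expect_equal(tz$mean_width, 31)                 # rows 11..41 inclusive
  expect_true(all(tz$width_profile == 31))
  expect_false(any(tz$interpolated))
  v <- tz$partition$values
  expect_true(all(v[1:10, ] == 2L))               # temperate north of band
  expect_true(all(v[11:41, ] == 1L))
  expect_true(all(v[42:50, ] == 0L))              # subtropical south
  # conservation: three zones partition all pixels
  expect_equal(sum(v == 0L) + sum(v == 1L) + sum(v == 2L), 50L * 40L)
})

test_that("coincident boundaries give the 1-cell degenerate band", {
  b <- extract_boundary(horizontal_zonemap(30, 20, 12))
  tz <- compose_transition(list(b, b, b), eco_grid(matrix(0, 30, 20))$geometry)
  expect_equal(tz$mean_width, 1)
  expect_equal(sum(tz$partition$values == 1L), 20L)
})

test_that("composition is symmetric in boundary-set order and brackets inputs", {
  fx <- band_fixture(rows = c(25, 8, 33))
  tz1 <- compose_transition(fx$bsets, fx$gm)
  tz2 <- compose_transition(rev(fx$bsets), fx$gm)
  expect_equal(tz1$partition$values, tz2$partition$values)
  expect_equal(tz1$mean_width, tz2$mean_width)
  # every input boundary lies inside or on the band envelopes
  for (bs in fx$bsets) for (ln in bs$lines) {
    fr <- (fx$gm$origin_y - ln[, 2]) / fx$gm$cell_size
    frN <- (fx$gm$origin_y - tz1$north_boundary[, 2]) / fx$gm$cell_size
    frS <- (fx$gm$origin_y - tz1$south_boundary[, 2]) / fx$gm$cell_size
    expect_true(all(fr >= min(frN) - 1e-9 & fr <= max(frS) + 1e-9))
  }
})

test_that("columns without crossings are filled from the nearest column", {
  # boundary map crossing only the west half of the raster
  z <- matrix(0L, 30, 30)
  z[1:10, 1:15] <- 1L                 # temperate block in the NW only
  zmA <- horizontal_zonemap(30, 30, 0); zmA$values <- z
  zmB <- horizontal_zonemap(30, 30, 20)
  tz <- compose_transition(list(extract_boundary(zmA), extract_boundary(zmB)),
                           eco_grid(matrix(0, 30, 30))$geometry)
  expect_false(any(tz$interpolated[1:15]))
  # width is averaged only over crossing-bearing columns
  expect_equal(tz$mean_width, mean(tz$width_profile[!tz$interpolated]))
})

test_that("masks propagate and degenerate inputs error", {
  fx <- band_fixture(rows = c(10, 20))
  msk <- matrix(FALSE, 50, 40); msk[1:3, ] <- TRUE
  tz <- compose_transition(fx$bsets, fx$gm, mask = msk)
  expect_true(all(tz$partition$values[1:3, ] == -1L))
  expect_equal(sum(tz$partition$values != -1L), 50L * 40L - 3L * 40L)

  empty <- suppressWarnings(extract_boundary(horizontal_zonemap(10, 10, 0)))
  expect_error(compose_transition(list(empty, empty), fx$gm), "empty")
  expect_warning(compose_transition(list(fx$bsets[[1]], empty), fx$gm),
                 "fewer than 2")
})

test_that("the composed band recovers generated boundary offsets", {
  land <- small_landscape(seed = 17, shape = c(120, 100), pairs = 3,
                          occupancy = 0.25)
  vars <- land$truth$drivers
  bsets <- lapply(land$occurrences, function(occ) {
    ex <- extract_labeled_pixels(land$stack, occ, vars)
    zn <- fit_zoner(ex$features, ex$labels, zoner_config(seed = 5))
    extract_boundary(predict_zonemap(zn, land$stack, vars))
  })
  tz <- compose_transition(bsets, land$stack$geometry)
  true_band <- diff(range(unlist(land$truth$boundary_rows))) + 1
  expect_lt(abs(tz$mean_width - true_band) / true_band, 0.15)
})
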
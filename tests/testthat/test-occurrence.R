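square_poly <- function(x0, y0, x1, y1, veg_type)
  list(type = "polygon", veg_type = veg_type,
       rings = list(cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))))

pairII <- pair_spec("II", "Pinus massoniana forest", "Pinus tabuliformis forest")

test_that("pixel-center rasterization counts pixels exactly", {
  gm <- eco_grid(matrix(0, 10, 10))$geometry  # cell 1, NW corner (0, 10)
  feats <- structure(list(
    square_poly(0, 0, 3, 3, "Pinus massoniana forest"),   # SW 3x3 block
    square_poly(6, 6, 9, 9, "Pinus tabuliformis forest")  # NE-ish 3x3 block
  ), class = "eco_features")
  occ <- rasterize_occurrences(feats, gm, pairII)
  expect_equal(sum(occ$labels == 0L), 9L)
  expect_equal(sum(occ$labels == 1L), 9L)
  expect_equal(sum(occ$labels == -1L), 82L)
  # the subtropical square occupies the 3 southernmost rows, 3 western cols
  expect_true(all(occ$labels[8:10, 1:3] == 0L))
})

test_that("rasterization handles points, mixed pixels and missing classes", {
  gm <- eco_grid(matrix(0, 6, 6))$geometry
  pts <- data.frame(x = c(1.5, 4.5), y = c(1.5, 4.5),
                    veg_type = c("Pinus massoniana forest",
                                 "Pinus tabuliformis forest"))
  occ <- rasterize_occurrences(pts, gm, pairII)
  expect_equal(occ$labels[5, 2], 0L)   # y=1.5 -> row 5; x=1.5 -> col 2
  expect_equal(occ$labels[2, 5], 1L)
  expect_equal(sum(occ$labels >= 0L), 2L)

  # both classes claiming one pixel resolves to excluded (-1)
  both <- structure(list(
    square_poly(0, 0, 6, 6, "Pinus massoniana forest"),
    square_poly(2, 2, 4, 4, "Pinus tabuliformis forest")
  ), class = "eco_features")
  occ2 <- rasterize_occurrences(both, gm, pairII)
  expect_true(all(occ2$labels[3:4, 3:4] == -1L))
  expect_true(all(occ2$labels[c(1, 6), ] == 0L))

  expect_error(rasterize_occurrences(structure(list(), class = "eco_features"),
                                     gm, pairII), "unusable pair")
  one_class <- structure(list(square_poly(0, 0, 3, 3, "Pinus massoniana forest")),
                         class = "eco_features")
  expect_error(rasterize_occurrences(one_class, gm, pairII), "unusable pair")
})

test_that("GeoJSON occurrence features survive a disk round-trip", {
  gm <- eco_grid(matrix(0, 10, 10))$geometry
  pts <- data.frame(x = c(2.5, 7.5, 7.5), y = c(2.5, 7.5, 6.5),
                    veg_type = c("Pinus massoniana forest",
                                 "Pinus tabuliformis forest",
                                 "Pinus tabuliformis forest"))
  pth <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(pts, pth)
  feats <- read_geojson(pth)
  occ <- rasterize_occurrences(feats, gm, pairII)
  expect_equal(sum(occ$labels == 0L), 1L)
  expect_equal(sum(occ$labels == 1L), 2L)
})

test_that("labeled-pixel extraction respects masks, order and counts", {
  v1 <- matrix(as.numeric(1:16), 4, 4)
  v2 <- matrix(as.numeric(101:116), 4, 4)
  v2[2, 1] <- NA
  st <- make_stack(a = v1, b = v2)
  lab <- matrix(-1L, 4, 4)
  lab[1, 1] <- 0L; lab[2, 1] <- 0L; lab[1, 2] <- 1L; lab[4, 4] <- 1L
  occ <- veg_occurrence(lab, pairII, st$geometry)

  ex <- extract_labeled_pixels(st, occ, c("a", "b"))
  expect_equal(nrow(ex$features), 3L)          # the masked pixel (2,1) dropped
  expect_equal(ex$pixels, c(1L, 2L, 16L))      # row-major indices
  expect_equal(ex$labels, c(0L, 1L, 1L))
  expect_equal(ex$features[, "a"], c(v1[1, 1], v1[1, 2], v1[4, 4]))

  # mask only counts for requested variables
  ex_a <- extract_labeled_pixels(st, occ, "a")
  expect_equal(nrow(ex_a$features), 4L)

  # row count identity: labeled minus masked-in-requested
  expect_equal(nrow(ex$features),
               sum(lab %in% c(0L, 1L)) - sum(lab >= 0L & is.na(v2)))

  expect_error(extract_labeled_pixels(st, occ, "zzz"), "not in stack")
  lab2 <- matrix(-1L, 4, 4)
  lab2[2, 1] <- 0L
  occ2 <- veg_occurrence(lab2, pairII, st$geometry)
  expect_error(extract_labeled_pixels(st, occ2, c("a", "b")),
               "no training pixels")
})
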
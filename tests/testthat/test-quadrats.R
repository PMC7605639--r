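test_that("survey counts are graded by the published inclusive bins", {
  rec <- data.frame(
    x = 0, y = 0,
    species = c("Platycarya strobilacea", "Pinus tabuliformis",
                "Pinus massoniana", "Platycarya strobilacea",
                "Pinus tabuliformis", "Pinus massoniana"),
    count = c(5, 21, 1, 98, 10, 11))
  g <- grade_quadrats(rec)
  expect_equal(as.character(g$grade),
               c("moderate", "high", "ungraded", "high", "low", "high"))
  # grading is total: every record gets exactly one grade
  expect_false(any(is.na(g$grade)))
})

test_that("out-of-bin counts and unknown species fall to ungraded", {
  rec <- data.frame(x = 0, y = 0,
                    species = c("Pinus tabuliformis", "Pinus tabuliformis",
                                "Betula sp."),
                    count = c(1, 61, 10))
  expect_warning(g <- grade_quadrats(rec), "Betula")
  expect_equal(as.character(g$grade), rep("ungraded", 3))
  expect_error(grade_quadrats(data.frame(x = 0, y = 0, species = "a",
                                         count = -1)), "non-negative")
  # custom bins must be disjoint and ordered
  expect_error(grade_bins("x", c(2, 5), c(4, 10), c(11, 20)), "disjoint")
  expect_error(grade_bins("x", c(5, 2), c(6, 10), c(11, 20)), "lo <= hi")
})

test_that("graded quadrats overlay onto zones with consistency fractions", {
  # partition: temperate rows 1-10, transition 11-20, subtropical 21-30
  v <- matrix(0L, 30, 30)
  v[1:10, ] <- 2L; v[11:20, ] <- 1L
  part <- structure(list(values = v,
                         geometry = eco_grid(matrix(0, 30, 30))$geometry),
                    class = "eco_partition")
  rec <- data.frame(
    x = c(5, 6, 7, 5, 6, 50),
    y = c(5, 5, 15, 25, 25, 5),     # y<10 south (subtropical); y>20 north
    species = c("Pinus massoniana", "Pinus massoniana", "Pinus massoniana",
                "Pinus tabuliformis", "Pinus tabuliformis",
                "Pinus massoniana"),
    count = c(12, 5, 3, 25, 30, 40))
  g <- grade_quadrats(rec)
  expect_warning(ov <- overlay_consistency(g, part), "skipped")
  expect_equal(ov$n_skipped, 1L)                 # the x = 50 record
  expect_equal(ov$n_used, 5L)
  # subtropical indicator in subtropical+transition zones: all 3 used records
  expect_equal(unname(ov$consistency[["Pinus massoniana"]]), 1)
  expect_equal(unname(ov$consistency[["Pinus tabuliformis"]]), 1)
  expect_equal(sum(ov$table), 5)

  # a temperate indicator deep in the subtropical zone is inconsistent
  bad <- grade_quadrats(data.frame(x = 5, y = 5,
                                   species = "Pinus tabuliformis", count = 25))
  ov2 <- overlay_consistency(bad, part)
  expect_equal(unname(ov2$consistency[["Pinus tabuliformis"]]), 0)

  # zero records: empty summary, no error
  ov0 <- overlay_consistency(rec[0, c("x", "y", "species")] |>
                               transform(grade = factor(character(0))), part)
  expect_equal(ov0$n_used, 0L)
})

test_that("synthetic quadrat surveys match their generating occupancy model", {
  tr <- synthetic_truth(seed = 6)
  qd <- generate_quadrats(tr, n_quadrats = 121)
  expect_equal(nrow(qd), 121L)
  expect_identical(qd, generate_quadrats(tr, n_quadrats = 121))

  # counts decay past the species' boundary: subtropical indicators are
  # near-zero well north of it, at plateau well south of it
  big <- generate_quadrats(tr, n_quadrats = 4000, seed = 99)
  sub <- big[big$species == "Pinus massoniana", ]
  r <- 200 - sub$y                                 # fractional row from north
  b <- tr$boundary_rows[[2]]                       # its pair's boundary
  far_north <- sub$count[r < b - 25]
  far_south <- sub$count[r > b + 25]
  expect_gte(mean(far_north == 0), 0.95)
  expect_gt(mean(far_south), 0.8 * tr$lam_max[["subtropical"]])

  # graded overlay against the true partition is highly consistent
  v <- matrix(0L, 200, 200)
  v[seq_len(85), ] <- 2L; v[86:116, ] <- 1L
  part <- structure(list(values = v,
                         geometry = eco_grid(matrix(0, 200, 200))$geometry),
                    class = "eco_partition")
  ov <- overlay_consistency(grade_quadrats(big), part)
  expect_true(all(ov$consistency >= 0.9))
})
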
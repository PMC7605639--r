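# shared fixtures and independent oracles used across test files

# independent brute-force eta-squared: explicit between/total sums of squares
oracle_eta2 <- function(y, h) {
  ybar <- sum(y) / length(y)
  sst <- sum((y - ybar)^2)
  if (sst == 0) return(0)
  ssb <- 0
  for (lev in unique(h)) {
    yk <- y[h == lev]
    ssb <- ssb + length(yk) * (sum(yk) / length(yk) - ybar)^2
  }
  ssb / sst
}

# brute-force count of 4-neighbour pixel edges separating a 0 from a 1
oracle_boundary_edges <- function(z) {
  n <- 0L
  nr <- nrow(z); nc <- ncol(z)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (c < nc && ((z[r, c] == 0 && z[r, c + 1] == 1) ||
                   (z[r, c] == 1 && z[r, c + 1] == 0))) n <- n + 1L
    if (r < nr && ((z[r, c] == 0 && z[r + 1, c] == 1) ||
                   (z[r, c] == 1 && z[r + 1, c] == 0))) n <- n + 1L
  }
  n
}

# stack of plain matrices sharing the default local geometry
make_stack <- function(...) {
  mats <- list(...)
  covariate_stack(lapply(mats, eco_grid))
}

# zone map with the top `btop` rows temperate (1) and the rest subtropical (0)
horizontal_zonemap <- function(nr, nc, btop, pair = NULL) {
  z <- matrix(0L, nr, nc)
  if (btop >= 1) z[seq_len(btop), ] <- 1L
  structure(list(values = z,
                 geometry = eco_grid(matrix(0, nr, nc))$geometry,
                 pair = pair, index_system = NULL),
            class = "eco_zonemap")
}

# small fully observed landscape for cheap recovery checks
small_landscape <- function(seed = 1, shape = c(60, 60), pairs = 1,
                            occupancy = 1, noise_sd = NULL) {
  ps <- list(pair_spec("I", "Quercus fabri forest", "Quercus wutaishanica forest"),
             pair_spec("II", "Pinus massoniana forest", "Pinus tabuliformis forest"),
             pair_spec("III", "Cyclobalanopsis glauca forest", "Populus davidiana forest"))
  args <- list(shape = shape, pairs = ps[seq_len(pairs)],
               occupancy_rate = occupancy, seed = seed)
  if (!is.null(noise_sd)) args$noise_sd <- noise_sd
  generate_landscape(do.call(synthetic_truth, args))
}
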
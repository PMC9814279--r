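test_that("neutral surfaces have exactly zero Coulomb energy", {
  s <- build_hexagonal(3, 2, q = 0)
  w <- place_water(c(0.3, 0.4, 0.3), axis = c(0.2, -1, 0.4))
  e <- pair_energy(w, s)
  expect_identical(e$coulomb, 0)
  expect_equal(e$total, e$lj)
})

test_that("LJ term vanishes at the sigma crossing above an isolated atom", {
  m <- spce_water()
  sig_os <- (m$sigmaO + 0.34) / 2
  s <- surface(data.frame(label = "A", x = 2, y = 2, z = 0, charge = 0,
                          epsilon = 0.2325, sigma = 0.34),
               cell = c(4, 4))
  w <- place_water(c(2, 2, sig_os))
  expect_equal(pair_energy(w, s)$lj, 0, tolerance = 1e-12)
})

test_that("pair energy matches a brute-force double-loop sum", {
  s <- two_atom_surface(q = 0.25)
  for (pose in list(c(1.2, 0.9, 0.31), c(3.5, 3.9, 0.45))) {
    w <- place_water(pose, axis = c(0.3, 0.2, -1), psi = 0.7)
    e <- pair_energy(w, s)
    b <- brute_energy(w, s)
    expect_equal(e$lj, b$lj, tolerance = 1e-12)
    expect_equal(e$coulomb, b$coulomb, tolerance = 1e-12)
    expect_equal(e$total, b$total, tolerance = 1e-12)
  }
})

test_that("overlapping poses are flagged but still return an energy", {
  s <- two_atom_surface()
  w <- place_water(c(1.0, 1.0, 0.02))
  e <- pair_energy(w, s)
  expect_true(e$overlap)
  expect_true(is.finite(e$total))
})

test_that("cutoff growth leaves LJ alone and only adds far Coulomb pairs", {
  s <- two_atom_surface(q = 0.3, cell = c(6, 6))
  # all six site-atom distances below 1.0 nm: both cutoffs see every pair
  w_near <- place_water(c(1.4, 1.2, 0.35))
  e1 <- pair_energy(w_near, s, cutoff = 1.0)
  e2 <- pair_energy(w_near, s, cutoff = 2.5)
  expect_equal(e2$coulomb, e1$coulomb, tolerance = 1e-14)
  expect_equal(e2$lj, e1$lj, tolerance = 1e-14)
  # a pose with pairs between 1.0 and 2.5 nm picks up extra Coulomb terms,
  # while LJ (fully inside its own 1.0 nm range) is unchanged
  w_far <- place_water(c(1.0, 1.0, 0.6))
  f1 <- pair_energy(w_far, s, cutoff = 1.0, cutoff_lj = 1.0)
  f2 <- pair_energy(w_far, s, cutoff = 2.5, cutoff_lj = 1.0)
  expect_false(identical(f1$coulomb, f2$coulomb))
  expect_equal(f2$lj, f1$lj, tolerance = 1e-12)
})

test_that("first-layer selection uses the half-open (0, 0.5] slab", {
  s <- build_square(4, 4)
  expect_length(select_first_layer(slab_frame(c(1.0, 1.2)), s), 0)
  expect_length(select_first_layer(slab_frame(0.50), s), 1)   # boundary in
  zs <- c(0.05, 0.2, 0.35, 0.5, 0.500001, 0.7, 1.4)
  got <- select_first_layer(slab_frame(zs), s)
  expect_length(got, sum(zs > 0 & zs <= 0.5))
})

test_that("a single observation fills exactly one grid cell with its energy", {
  s <- build_square(4, 4)
  w <- place_water(c(0.31, 0.62, 0.3))
  g <- accumulate_map(list(list(w)), s, n = c(10, 10))
  expect_equal(sum(!is.na(g$values)), 1)
  expect_equal(g$values[4, 7], pair_energy(w, s)$total)
  expect_equal(sum(g$counts), 1)
})

test_that("map occupancy counts equal the number of first-layer observations", {
  s <- build_square(4, 4, q = 0.2)
  set.seed(3)
  frames <- replicate(4, lapply(seq_len(12), function(i)
    place_water(c(runif(1, 0, 1), runif(1, 0, 1), runif(1, 0.1, 0.9)),
                axis = rnorm(3))), simplify = FALSE)
  n_layer <- sum(vapply(frames, function(f)
    length(select_first_layer(f, s)), numeric(1)))
  g <- accumulate_map(frames, s, n = c(20, 20))
  expect_equal(sum(g$counts), n_layer)
})

test_that("an incommensurate grid edge errors and suggests an alternative", {
  s <- build_hexagonal(2, 2)
  expect_error(accumulate_map(list(slab_frame(0.3)), s, cell_edge = 0.05),
               "commensurate")
  expect_error(probe_map(s, cell_edge = 0.07), "commensurate")
})

test_that("probe map with one orientation is the plain pair-energy field", {
  s <- build_square(2, 2, q = 0.2)
  g <- probe_map(s, z_probe = 0.3, n = c(4, 4), n_orient = 1)
  ors <- surfriction:::.orientation_set(1)
  # recompute one arbitrary cell centre by hand
  cellc <- c((2 - 0.5) * 0.125, (3 - 0.5) * 0.125, 0.3)
  w <- place_water(cellc, axis = ors$axis[1, ], psi = ors$psi[1])
  expect_equal(g$values[2, 3], pair_energy(w, s)$total, tolerance = 1e-10)
})

test_that("the Coulomb probe field is exactly linear in q (uniform weights)", {
  mk <- function(q) probe_map(build_square(4, 4, q = q), n = c(8, 8),
                              n_orient = 6, weighting = "uniform")
  g1 <- mk(0.15); g2 <- mk(0.30)
  expect_equal(g2$coulomb, 2 * g1$coulomb, tolerance = 1e-12)
  expect_equal(g2$lj, g1$lj, tolerance = 1e-12)
})

test_that("probe maps are invariant under lattice translations", {
  s <- build_hexagonal(3, 2, q = 0.25)
  a <- s$metadata$bond_length
  shifted <- translate_surface(s, c(sqrt(3) * a, 0))  # one unit cell in x
  g1 <- probe_map(s, n = c(9, 8), n_orient = 4)
  g2 <- probe_map(shifted, n = c(9, 8), n_orient = 4)
  expect_equal(g2$values, g1$values, tolerance = 1e-8)
})

test_that("map statistics match hand arithmetic and q^2 scaling", {
  g <- surfriction:::.new_energy_grid(matrix(c(1, 2, 3, 6), 2, 2),
                                      matrix(0, 2, 2), matrix(0, 2, 2),
                                      matrix(1, 2, 2), c(0.05, 0.05),
                                      c(0.1, 0.1), "test")
  st <- map_stats(g)
  expect_equal(st$mean_E, 3)
  expect_equal(st$var_E, mean((c(1, 2, 3, 6) - 3)^2))  # population variance
  # constant map
  gc <- surfriction:::.new_energy_grid(matrix(2, 2, 2), matrix(0, 2, 2),
                                       matrix(0, 2, 2), matrix(1, 2, 2),
                                       c(0.05, 0.05), c(0.1, 0.1), "test")
  expect_equal(map_stats(gc)$var_E, 0)
  expect_error(map_stats(surfriction:::.new_energy_grid(
    matrix(c(1, NA, NA, NA), 2, 2), matrix(0, 2, 2), matrix(0, 2, 2),
    matrix(1, 2, 2), c(0.05, 0.05), c(0.1, 0.1), "test")), "2 occupied")
  # Coulomb-only variance quadruples when q doubles
  mk <- function(q) probe_map(build_hexagonal(3, 2, q = q), n = c(9, 8),
                              n_orient = 6, weighting = "uniform")
  v1 <- map_stats(mk(0.1), component = "coulomb")$var_E
  v2 <- map_stats(mk(0.2), component = "coulomb")$var_E
  expect_equal(v2 / v1, 4, tolerance = 1e-9)
})

test_that("the E_micro histogram broadens as q grows", {
  sds <- vapply(c(0, 0.1, 0.2, 0.3), function(q)
    map_stats(probe_map(build_square(4, 4, q = q), n = c(8, 8), n_orient = 6,
                        weighting = "uniform"))$sd_E, numeric(1))
  expect_true(all(diff(sds) >= -1e-12))
})

test_that("interface energy density is intensive and matches a direct sum", {
  s <- build_square(4, 4, q = 0.2)
  w <- place_water(c(0.3, 0.3, 0.35))
  expect_equal(interface_energy_density(list(list(w)), s),
               pair_energy(w, s)$total / cell_area(s))
  # doubling cell and waters leaves the density unchanged; the cutoff must
  # stay below half the smaller cell so both systems see the same images
  s2 <- build_square(8, 4, q = 0.2)
  w2 <- place_water(c(0.3 + 1.0, 0.3, 0.35))
  expect_equal(interface_energy_density(list(list(w, w2)), s2, cutoff = 0.45,
                                        cutoff_lj = 0.45),
               interface_energy_density(list(list(w)), s, cutoff = 0.45,
                                        cutoff_lj = 0.45),
               tolerance = 1e-9)
  # brute-force slab oracle, including waters above the first layer
  set.seed(7)
  slab <- lapply(1:6, function(i)
    place_water(c(runif(1, 0, 1), runif(1, 0, 1), runif(1, 0.25, 1.5)),
                axis = rnorm(3)))
  direct <- sum(vapply(slab, function(w) brute_energy(w, s)$total,
                       numeric(1))) / cell_area(s)
  expect_equal(interface_energy_density(list(slab), s), direct,
               tolerance = 1e-10)
})
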
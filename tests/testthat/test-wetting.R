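# hand-built density field helper: rho[i, j] over given edges
fake_field <- function(rho, r_edges, z_edges) {
  structure(list(rho = rho, counts = rho, r_edges = r_edges,
                 z_edges = z_edges, axis = c(0, 0), n_frames = 1),
            class = "density_field")
}

test_that("density field of a single molecule occupies one bin per frame", {
  f <- density_field(list(matrix(c(0.31, 0.52, 1.03), 1, 3)), dr = 0.1,
                     dz = 0.05)
  expect_equal(sum(f$rho > 0), 1)
})

test_that("interior of a uniform cylinder slab is flat across r", {
  set.seed(2)
  n <- 200000
  r <- sqrt(runif(n)) * 2
  ang <- runif(n, 0, 2 * pi)
  pts <- cbind(r * cos(ang), r * sin(ang), runif(n, 0, 1))
  f <- density_field(list(pts), dr = 0.2, dz = 0.25)
  rc <- (f$r_edges[-1] + head(f$r_edges, -1)) / 2
  row <- f$rho[rc < 1.8, 2]
  expect_lt(max(abs(row / mean(row) - 1)), 0.1)
})

test_that("a sharp step profile yields interface points exactly at the edge", {
  r_edges <- seq(0, 4, by = 0.1)
  z_edges <- seq(0, 2, by = 0.1)
  rc <- (r_edges[-1] + head(r_edges, -1)) / 2
  rho <- matrix(0, length(rc), length(z_edges) - 1)
  rho[rc < 2.0, ] <- 10       # edge at r = 2.0, a bin boundary
  pts <- extract_interface(fake_field(rho, r_edges, z_edges),
                           z_exclude = 0.5, rho_bulk = 10)
  expect_true(all(abs(pts$r - 2.0) < 1e-12))
})

test_that("a tanh-smoothed edge is located at its midpoint within half a bin", {
  r_edges <- seq(0, 4, by = 0.1)
  z_edges <- seq(0, 1.6, by = 0.1)
  rc <- (r_edges[-1] + head(r_edges, -1)) / 2
  prof <- 10 * (1 - tanh((rc - 2.37) / 0.3)) / 2
  rho <- matrix(prof, length(rc), length(z_edges) - 1)
  pts <- extract_interface(fake_field(rho, r_edges, z_edges),
                           z_exclude = 0.5, rho_bulk = 10)
  expect_true(all(abs(pts$r - 2.37) < 0.05))
})

test_that("a profile with no outward density drop is rejected", {
  r_edges <- seq(0, 2, by = 0.1)
  z_edges <- seq(0, 1.5, by = 0.1)
  rc <- (r_edges[-1] + head(r_edges, -1)) / 2
  rho <- matrix(rc, length(rc), length(z_edges) - 1)  # increasing in r
  expect_error(extract_interface(fake_field(rho, r_edges, z_edges),
                                 rho_bulk = 1),
               "not a droplet")
})

test_that("points on a circle crossing the contact plane vertically give 90 degrees", {
  phi <- seq(0.05, pi / 2, length.out = 40)
  pts <- data.frame(r = 3 * sin(phi) + 1e-9 * rnorm(40),
                    z = 1.0 + 3 * cos(phi))
  ca <- fit_contact_angle(pts, z_contact = 1.0, z_exclude = 0)
  expect_equal(ca$theta, 90, tolerance = 1e-4)
  expect_equal(ca$radius, 3, tolerance = 1e-4)
})

test_that("collinear interface points are a degenerate circle fit", {
  pts <- data.frame(r = seq(1, 2, length.out = 10), z = seq(1, 3, length.out = 10))
  expect_error(fit_contact_angle(pts, z_exclude = 0), "collinear")
  expect_error(fit_contact_angle(pts[1:3, ], z_exclude = 0), "at least 5")
})

test_that("synthetic caps are recovered closed-loop at one angle", {
  fr <- gen_droplet(95, R = 6, n_samples = 1e6, n_frames = 20, seed = 31)
  ca <- contact_angle_from_frames(fr)
  expect_equal(ca$theta, 95, tolerance = 0.01)  # within about a degree
})

test_that("fitted angle is invariant under droplet rescaling", {
  th <- 110
  ca1 <- contact_angle_from_frames(
    gen_droplet(th, R = 4, n_samples = 2e6, n_frames = 1, seed = 8))
  ca2 <- contact_angle_from_frames(
    gen_droplet(th, R = 8, n_samples = 2e6, n_frames = 1, seed = 8))
  expect_lt(abs(ca1$theta - ca2$theta), 0.5)
})

test_that("the angle is stable against the wall-exclusion height", {
  fr <- gen_droplet(80, R = 6, n_samples = 3e6, n_frames = 1, seed = 12)
  f <- density_field(fr)
  angles <- vapply(c(0.5, 0.75, 1.0), function(ze) {
    pts <- extract_interface(f, z_exclude = ze)
    fit_contact_angle(pts, z_exclude = ze)$theta
  }, numeric(1))
  expect_lt(max(angles) - min(angles), 1.0)
})

test_that("noisy angle recovery across a wide theta grid stays accurate", {
  grid <- c(50, 75, 100, 125, 140)
  errs <- vapply(seq_along(grid), function(i) {
    fr <- gen_droplet(grid[i], R = 6, n_samples = 1e6, n_frames = 20,
                      noise = 0.03, seed = 40 + i)
    contact_angle_from_frames(fr)$theta - grid[i]
  }, numeric(1))
  expect_lt(mean(abs(errs)), 2)
})

test_that("the Huang relation has the right symmetry, monotonicity and limits", {
  expect_equal(huang_relative_friction(73, 73), 1)
  expect_equal(huang_relative_friction(90, 90), 1)
  th <- seq(10, 170, by = 10)
  vals <- huang_relative_friction(th, 90)
  expect_true(all(diff(vals) < 0))
  expect_lt(huang_relative_friction(179.9, 90), 1e-5)
  expect_equal(huang_relative_friction(0.01, 90), 4, tolerance = 1e-4)
  expect_error(huang_relative_friction(0, 90), "between 0 and 180")
  expect_error(huang_relative_friction(90, 180), "between 0 and 180")
  # direct arithmetic at the two simulated end-point angles
  expect_equal(huang_relative_friction(68, 88),
               (1 + cos(68 * pi / 180))^2 / (1 + cos(88 * pi / 180))^2)
})
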
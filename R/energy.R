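#' Water-surface pair interaction energy
#'
#' Lennard-Jones plus Coulomb energy between one rigid water and all
#' surface atoms, under the minimum-image convention over the in-plane
#' periodic cell and a spherical cutoff (default 1.0 nm) applied to both
#' terms. The LJ term acts on the oxygen site only (the water model has no
#' hydrogen LJ site), with cross parameters from Lorentz-Berthelot rules
#' (arithmetic sigma, geometric epsilon) by default. Electrostatics is a
#' truncated direct sum; overall surface neutrality keeps the truncation
#' error bounded.
#'
#' @param water a `water_config` (3 x 3 site matrix, rows O, H1, H2).
#' @param surface a [surface].
#' @param cutoff Coulomb cutoff, nm.
#' @param cutoff_lj dispersion (LJ) cutoff, nm; fixed at 1.0 by default
#'   and independent of the Coulomb cutoff.
#' @param combining `"lorentz"` (arithmetic sigma) or `"geometric"`.
#' @param model water parameters, see [spce_water()].
#' @return list with `total`, `lj`, `coulomb` (kJ/mol) and `overlap`
#'   (TRUE when any site-atom distance is below 0.05 nm; the energy is
#'   still returned).
#' @examples
#' s <- build_square(2, 2, q = 0)
#' w <- place_water(c(0.1, 0.1, 0.3))
#' pair_energy(w, s)$coulomb  # 0: neutral surface
#' @export
pair_energy <- function(water, surface, cutoff = 1.0, cutoff_lj = 1.0,
                        combining = c("lorentz", "geometric"),
                        model = spce_water()) {
  combining <- match.arg(combining)
  f <- .site_field(as.matrix(water), c(model$qO, model$qH, model$qH),
                   c(TRUE, FALSE, FALSE), surface, cutoff, cutoff_lj,
                   combining, model)
  list(total = sum(f$lj) + sum(f$cb), lj = sum(f$lj), coulomb = sum(f$cb),
       overlap = f$min_r < 0.05)
}

# vectorised site-atom field: P (n_sites x 3), per-site charges and O flags
.site_field <- function(P, qs, iso, surface, cutoff, cutoff_lj, combining,
                        model) {
  a <- surface$atoms
  Lx <- surface$cell[1]; Ly <- surface$cell[2]
  dx <- outer(P[, 1], a$x, "-"); dx <- dx - Lx * round(dx / Lx)
  dy <- outer(P[, 2], a$y, "-"); dy <- dy - Ly * round(dy / Ly)
  dz <- outer(P[, 3], a$z, "-")
  r2 <- dx * dx + dy * dy + dz * dz
  r <- sqrt(r2)
  cb <- ke_kJmol_nm * outer(qs, a$charge) / r
  cb[r2 > cutoff^2] <- 0
  cb_site <- rowSums(cb)
  lj_site <- numeric(nrow(P))
  has_lj <- a$epsilon > 0
  if (any(iso) && any(has_lj)) {
    sig <- switch(combining,
                  lorentz = (model$sigmaO + a$sigma[has_lj]) / 2,
                  geometric = sqrt(model$sigmaO * a$sigma[has_lj]))
    eps <- sqrt(model$epsilonO * a$epsilon[has_lj])
    ro <- r[iso, has_lj, drop = FALSE]
    sr6 <- sweep(1 / ro, 2, sig, "*")^6
    ljp <- sweep(sr6 * sr6, 2, 4 * eps, "*") - sweep(sr6, 2, 4 * eps, "*")
    ljp[r2[iso, has_lj, drop = FALSE] > cutoff_lj^2] <- 0
    lj_site[iso] <- rowSums(ljp)
  }
  list(cb = cb_site, lj = lj_site, min_r = min(r))
}

#' Select first-contact-layer waters
#'
#' Returns the waters whose oxygen lies within the first contact layer,
#' the half-open slab (z_plane, z_plane + thickness] with thickness
#' 0.50 nm by default (the upper bound is included).
#'
#' @param frame a list of `water_config` objects or a site matrix with
#'   rows O, H1, H2 repeated per molecule.
#' @param surface a [surface].
#' @param thickness layer thickness, nm.
#' @return list of `water_config` objects (possibly empty).
#' @export
select_first_layer <- function(frame, surface, thickness = 0.50) {
  waters <- .group_waters(frame)
  oz <- vapply(waters, function(w) w[1, 3], numeric(1))
  keep <- oz > surface$z_plane & oz <= surface$z_plane + thickness
  waters[keep]
}

# grid dimensions from an edge length or explicit cell counts
.grid_dims <- function(cell, cell_edge = NULL, n = NULL, tol = 1e-6) {
  if (!is.null(n)) {
    n <- as.integer(rep_len(n, 2L))
    stopifnot(all(n >= 1L))
    return(list(n = n, edge = cell / n))
  }
  nx <- round(cell[1] / cell_edge); ny <- round(cell[2] / cell_edge)
  if (abs(nx * cell_edge - cell[1]) > tol || abs(ny * cell_edge - cell[2]) > tol)
    stop(sprintf(paste0(
      "grid edge %.6g nm is not commensurate with the %.6g x %.6g nm cell; ",
      "nearest commensurate edges are %.6g (x) and %.6g (y) nm, ",
      "or pass n = c(%d, %d)"),
      cell_edge, cell[1], cell[2], cell[1] / max(nx, 1), cell[2] / max(ny, 1),
      max(nx, 1), max(ny, 1)))
  list(n = c(nx, ny), edge = cell / c(nx, ny))
}

.new_energy_grid <- function(values, lj, coulomb, counts, edge, cell, source) {
  structure(list(values = values, lj = lj, coulomb = coulomb, counts = counts,
                 edge = edge, cell = cell, source = source),
            class = "energy_grid")
}

#' @export
print.energy_grid <- function(x, ...) {
  n <- dim(x$values)
  cat(sprintf("energy_grid (%s): %d x %d cells of %.4f x %.4f nm (%.3g A^2)\n",
              x$source, n[1], n[2], x$edge[1], x$edge[2],
              prod(x$edge) * 100))
  cat(sprintf("  %d/%d cells occupied; E_micro range [%.3f, %.3f] kJ/mol\n",
              sum(!is.na(x$values)), length(x$values),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Accumulate the microscopic energy map from trajectory frames
#'
#' For every first-layer water in every frame, computes [pair_energy()]
#' against the surface and bins it on a fine in-plane grid (default cell
#' area 0.25 A^2, i.e. 0.05 nm edge) by the oxygen (x, y); each grid cell
#' holds the mean of the energies observed in it. Cells never visited are
#' masked (`NA`), not zero-filled.
#'
#' @param frames list of frames (each a list of `water_config`s or a site
#'   matrix).
#' @param surface a [surface].
#' @param cell_edge grid cell edge, nm; must tile the periodic cell
#'   exactly or an error lists the nearest commensurate edge.
#' @param n alternative to `cell_edge`: explicit cell counts `c(nx, ny)`.
#' @param thickness first-layer thickness, nm.
#' @param average `"observation"` bins every instantaneous energy;
#'   `"molecule"` first averages each molecule over time (requires a fixed
#'   molecule count across frames) and bins once at its mean position.
#' @inheritParams pair_energy
#' @return An `energy_grid` with per-cell mean `values`, the `lj` and
#'   `coulomb` components, and observation `counts`.
#' @export
accumulate_map <- function(frames, surface, cell_edge = 0.05, n = NULL,
                           thickness = 0.50, cutoff = 1.0, cutoff_lj = 1.0,
                           combining = c("lorentz", "geometric"),
                           average = c("observation", "molecule"),
                           model = spce_water()) {
  combining <- match.arg(combining)
  average <- match.arg(average)
  g <- .grid_dims(surface$cell, cell_edge, n)
  nx <- g$n[1]; ny <- g$n[2]
  obs <- list()
  for (fi in seq_along(frames)) {
    waters <- .group_waters(frames[[fi]])
    oz <- vapply(waters, function(w) w[1, 3], numeric(1))
    keep <- which(oz > surface$z_plane & oz <= surface$z_plane + thickness)
    for (k in keep) {
      w <- waters[[k]]
      e <- pair_energy(w, surface, cutoff, cutoff_lj, combining, model)
      obs[[length(obs) + 1L]] <- c(w[1, 1], w[1, 2], e$total, e$lj, e$coulomb,
                                   k)
    }
  }
  if (length(obs) == 0)
    stop("no first-layer water observations in the trajectory")
  ob <- do.call(rbind, obs)
  if (average == "molecule") {
    sp <- split.data.frame(ob, ob[, 6])
    ob <- t(vapply(sp, colMeans, numeric(6)))
  }
  ix <- pmin(1L + floor((ob[, 1] %% surface$cell[1]) / g$edge[1]), nx)
  iy <- pmin(1L + floor((ob[, 2] %% surface$cell[2]) / g$edge[2]), ny)
  idx <- (iy - 1L) * nx + ix
  acc <- function(v) {
    s <- rep(NA_real_, nx * ny)
    t <- tapply(v, idx, mean)
    s[as.integer(names(t))] <- t
    matrix(s, nx, ny)
  }
  counts <- rep(0L, nx * ny)
  tc <- tapply(rep(1L, length(idx)), idx, sum)
  counts[as.integer(names(tc))] <- tc
  .new_energy_grid(acc(ob[, 3]), acc(ob[, 4]), acc(ob[, 5]),
                   matrix(counts, nx, ny), g$edge, surface$cell, "trajectory")
}

# deterministic quasi-uniform orientation set: Fibonacci-sphere bisector
# directions with a golden-angle spin about each
.orientation_set <- function(n_orient) {
  k <- seq_len(n_orient)
  ga <- pi * (3 - sqrt(5))
  z <- 1 - (2 * k - 1) / n_orient
  rr <- sqrt(pmax(0, 1 - z^2))
  phi <- ga * (k - 1)
  list(axis = cbind(rr * cos(phi), rr * sin(phi), z), psi = ga * k)
}

#' Deterministic probe map of the surface energy landscape
#'
#' A desk-scale stand-in for trajectory-accumulated maps: for every grid
#' cell centre, a rigid water is placed with its oxygen at height
#' `z_probe` and the pair energy is averaged over a fixed quasi-uniform
#' orientation quadrature (default 32 orientations). With
#' `weighting = "boltzmann"` (default) orientations are weighted by
#' exp(-E/kT) at `temperature`; `weighting = "uniform"` takes the plain
#' orientation mean, which keeps the Coulomb component exactly linear in
#' the surface charge q (the linear-response regime used by the q^2
#' scaling checks).
#'
#' @inheritParams accumulate_map
#' @param z_probe oxygen height above `z_plane`, nm; within the first
#'   layer, default 0.35 nm, near the oxygen-solid LJ minimum where the
#'   first-layer oxygens concentrate.
#' @param n_orient number of quadrature orientations (>= 1).
#' @param temperature Boltzmann temperature, K.
#' @param weighting `"boltzmann"` or `"uniform"`.
#' @return An `energy_grid` whose every cell is occupied.
#' @export
probe_map <- function(surface, z_probe = 0.35, cell_edge = 0.05, n = NULL,
                      n_orient = 32, temperature = 300,
                      weighting = c("boltzmann", "uniform"), cutoff = 1.0,
                      cutoff_lj = 1.0,
                      combining = c("lorentz", "geometric"),
                      model = spce_water()) {
  combining <- match.arg(combining)
  weighting <- match.arg(weighting)
  if (n_orient < 1) stop("orientation set is empty")
  g <- .grid_dims(surface$cell, cell_edge, n)
  nx <- g$n[1]; ny <- g$n[2]
  cx <- (seq_len(nx) - 0.5) * g$edge[1]
  cy <- (seq_len(ny) - 0.5) * g$edge[2]
  centers <- cbind(rep(cx, times = ny), rep(cy, each = nx),
                   surface$z_plane + z_probe)
  ncell <- nrow(centers)
  ors <- .orientation_set(n_orient)
  canon <- .water_canonical(model)
  qs1 <- c(model$qO, model$qH, model$qH)
  Etot <- Elj <- Ecb <- matrix(0, ncell, n_orient)
  for (k in seq_len(n_orient)) {
    sites1 <- canon %*% t(.rot_to(ors$axis[k, ], ors$psi[k]))
    P <- centers[rep(seq_len(ncell), each = 3L), , drop = FALSE] +
      sites1[rep(1:3, times = ncell), , drop = FALSE]
    f <- .site_field(P, rep(qs1, times = ncell),
                     rep(c(TRUE, FALSE, FALSE), times = ncell),
                     surface, cutoff, cutoff_lj, combining, model)
    grp <- rep(seq_len(ncell), each = 3L)
    Elj[, k] <- as.numeric(rowsum(f$lj, grp))
    Ecb[, k] <- as.numeric(rowsum(f$cb, grp))
    Etot[, k] <- Elj[, k] + Ecb[, k]
  }
  if (weighting == "boltzmann") {
    beta <- 1 / (kB_kJmol * temperature)
    wmat <- exp(-beta * (Etot - apply(Etot, 1, min)))
    wmat <- wmat / rowSums(wmat)
  } else {
    wmat <- matrix(1 / n_orient, ncell, n_orient)
  }
  val <- function(E) matrix(rowSums(E * wmat), nx, ny)
  .new_energy_grid(val(Etot), val(Elj), val(Ecb),
                   matrix(n_orient, nx, ny), g$edge, surface$cell,
                   paste0("probe-", weighting))
}

#' Mean, variance and histogram of the microscopic energy map
#'
#' The corrugation statistic is the population variance of E_micro over
#' the occupied grid cells, (Delta E_micro)^2 = <(E_micro - <E_micro>)^2>.
#' `weighting = "cell"` (default) treats every occupied cell equally —
#' the standard deviation of the map itself; `"occupancy"` weights cells
#' by their observation counts.
#'
#' @param grid an `energy_grid`.
#' @param weighting `"cell"` or `"occupancy"`.
#' @param component which energy component to summarise.
#' @param bin_width histogram bin width, kJ/mol.
#' @return list of class `map_stats` with `mean_E`, `var_E`, `sd_E`,
#'   `histogram` (data frame `mid`, `count`), `n_cells`.
#' @export
map_stats <- function(grid, weighting = c("cell", "occupancy"),
                      component = c("total", "coulomb", "lj"),
                      bin_width = 0.05) {
  weighting <- match.arg(weighting)
  component <- match.arg(component)
  v <- switch(component, total = grid$values, coulomb = grid$coulomb,
              lj = grid$lj)
  ok <- !is.na(v)
  if (sum(ok) < 2) stop("map_stats needs at least 2 occupied cells")
  x <- v[ok]
  w <- if (weighting == "occupancy") grid$counts[ok] else rep(1, length(x))
  w <- w / sum(w)
  m <- sum(w * x)
  var_E <- sum(w * (x - m)^2)
  breaks <- seq(floor(min(x) / bin_width) * bin_width,
                ceiling(max(x) / bin_width) * bin_width + bin_width / 2,
                by = bin_width)
  bin <- findInterval(x, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  structure(list(mean_E = m, var_E = var_E, sd_E = sqrt(var_E),
                 histogram = data.frame(mid = breaks[-1] - bin_width / 2,
                                        count = counts),
                 n_cells = length(x), weighting = weighting,
                 component = component),
            class = "map_stats")
}

#' @export
print.map_stats <- function(x, ...) {
  cat(sprintf(paste0("map_stats (%s, %s-weighted, %d cells):\n",
                     "  <E_micro> = %.4f kJ/mol, (dE_micro)^2 = %.6g",
                     " (kJ/mol)^2, dE_micro = %.4f kJ/mol\n"),
              x$component, x$weighting, x$n_cells, x$mean_E, x$var_E, x$sd_E))
  invisible(x)
}

#' Total solid-water interaction energy per unit area
#'
#' Frame-averaged sum of [pair_energy()] over all waters (not only the
#' first layer), divided by the in-plane cell area.
#'
#' @inheritParams accumulate_map
#' @return energy density, kJ mol^-1 nm^-2.
#' @export
interface_energy_density <- function(frames, surface, cutoff = 1.0,
                                     cutoff_lj = 1.0,
                                     combining = c("lorentz", "geometric"),
                                     model = spce_water()) {
  combining <- match.arg(combining)
  area <- cell_area(surface)
  if (area <= 0) stop("surface cell has zero area")
  if (length(frames) == 0) stop("empty trajectory")
  per_frame <- vapply(frames, function(fr) {
    waters <- .group_waters(fr)
    sum(vapply(waters, function(w)
      pair_energy(w, surface, cutoff, cutoff_lj, combining,
                  model)$total, numeric(1)))
  }, numeric(1))
  mean(per_frame) / area
}
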
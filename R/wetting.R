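#' Cylindrical number-density field of a sessile droplet
#'
#' Bins molecule positions into a cylindrical (r, z) histogram about the
#' droplet's symmetry axis — the time-averaged in-plane centre of mass —
#' and normalises by shell volume and frame count to a number density in
#' nm^-3.
#'
#' @param frames list of frames; each frame is an n x 3 matrix of
#'   molecule (oxygen) positions in nm, or a list of `water_config`s.
#' @param dr,dz radial and vertical bin widths, nm (defaults 0.1 and
#'   0.05).
#' @param r_max,z_max histogram extents, nm; derived from the data when
#'   missing.
#' @return object of class `density_field` with `rho` (nr x nz matrix,
#'   nm^-3), `r_edges`, `z_edges`, `axis`, `n_frames`.
#' @export
density_field <- function(frames, dr = 0.1, dz = 0.05, r_max = NULL,
                          z_max = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) == 0) stop("empty trajectory")
  pts <- lapply(frames, .o_positions)
  com <- colMeans(do.call(rbind, lapply(pts, function(p)
    colMeans(p[, 1:2, drop = FALSE]))))
  all <- do.call(rbind, pts)
  r <- sqrt((all[, 1] - com[1])^2 + (all[, 2] - com[2])^2)
  z <- all[, 3]
  if (is.null(r_max)) r_max <- max(r) + dr
  if (is.null(z_max)) z_max <- max(z) + dz
  r_edges <- seq(0, r_max + dr, by = dr)
  z_edges <- seq(0, z_max + dz, by = dz)
  ir <- findInterval(r, r_edges, rightmost.closed = TRUE)
  iz <- findInterval(z, z_edges, rightmost.closed = TRUE)
  ok <- ir >= 1 & ir < length(r_edges) & iz >= 1 & iz < length(z_edges)
  nr <- length(r_edges) - 1L; nz <- length(z_edges) - 1L
  counts <- matrix(tabulate((iz[ok] - 1L) * nr + ir[ok], nbins = nr * nz),
                   nr, nz)
  shell <- pi * (r_edges[-1]^2 - r_edges[-length(r_edges)]^2) * dz
  rho <- counts / (shell * length(frames))
  structure(list(rho = rho, counts = counts, r_edges = r_edges,
                 z_edges = z_edges, axis = com, n_frames = length(frames)),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf(paste0("density_field: %d x %d (r x z) bins, %d frame(s), ",
                     "max rho = %.3g nm^-3\n"),
              nrow(x$rho), ncol(x$rho), x$n_frames, max(x$rho)))
  invisible(x)
}

#' Extract the liquid-vapor interface as isodensity points
#'
#' For every z-row of the density field above `z_exclude` (the layered
#' region near the wall is skipped), finds the radius where the density
#' falls through `threshold_fraction` times the bulk density, by linear
#' interpolation between bin centres. The bulk density is estimated from
#' interior bins (r below half the droplet radius, over the middle half
#' of the occupied z-rows) unless supplied.
#'
#' @param field a [density_field()].
#' @param threshold_fraction isodensity level as a fraction of bulk
#'   (default 0.5).
#' @param z_exclude exclusion height above the wall, nm.
#' @param rho_bulk bulk number density, nm^-3; estimated when `NULL`.
#' @param min_interior rows whose mean density inside the crossing does
#'   not reach this fraction of bulk are dropped: near the droplet apex
#'   the profile no longer cuts through bulk liquid and the isodensity
#'   radius degenerates.
#' @return data frame with columns `r`, `z` (nm) plus attribute
#'   `rho_bulk`.
#' @export
extract_interface <- function(field, threshold_fraction = 0.5,
                              z_exclude = 0.8, rho_bulk = NULL,
                              min_interior = 0.8) {
  rho <- field$rho
  rc <- (field$r_edges[-1] + field$r_edges[-length(field$r_edges)]) / 2
  zc <- (field$z_edges[-1] + field$z_edges[-length(field$z_edges)]) / 2
  if (is.null(rho_bulk)) {
    # robust density reference: small inner shells are noisy, so use a high
    # quantile of the occupied bins rather than the single maximum
    rmax_half <- unname(stats::quantile(rho[rho > 0], 0.95)) / 2
    occ_rows <- which(apply(rho, 2, max) > rmax_half)
    if (length(occ_rows) < 2) stop("droplet interior too small to estimate bulk density")
    band <- occ_rows[occ_rows >= stats::quantile(occ_rows, 0.25) &
                     occ_rows <= stats::quantile(occ_rows, 0.75)]
    r_extent <- max(rc[apply(rho[, band, drop = FALSE] > rmax_half, 1, any)])
    interior <- rho[rc < 0.5 * r_extent, band, drop = FALSE]
    if (length(interior) == 0) stop("no interior bins for bulk density")
    rho_bulk <- mean(interior)
  }
  thr <- threshold_fraction * rho_bulk
  pts <- list()
  for (j in which(zc > z_exclude)) {
    v <- rho[, j]
    above <- which(v >= thr)
    if (length(above) == 0) next
    i <- max(above)
    if (i >= length(v)) next  # density never falls below threshold outward
    if (mean(v[seq_len(i)]) < min_interior * rho_bulk) next  # apex row
    # linear interpolation between bin centres i and i+1
    r_cross <- rc[i] + (thr - v[i]) / (v[i + 1] - v[i]) * (rc[i + 1] - rc[i])
    pts[[length(pts) + 1L]] <- c(r_cross, zc[j])
  }
  if (length(pts) == 0)
    stop("no liquid-vapor crossing found in any z-row: not a droplet profile")
  out <- as.data.frame(do.call(rbind, pts))
  names(out) <- c("r", "z")
  attr(out, "rho_bulk") <- rho_bulk
  out
}

#' Fit a circle to interface points and extract the contact angle
#'
#' Least-squares circle through the (r, z) interface points above
#' `z_exclude`: an algebraic (Kasa) fit provides the starting point and
#' is then refined by minimising the orthogonal distance sum of squares
#' (the algebraic fit systematically underestimates the radius on short
#' noisy arcs). The contact angle is the angle between the circle's
#' tangent at the contact height `z_contact` and the surface plane,
#' measured through the liquid.
#'
#' @param points data frame with `r`, `z` columns, nm (e.g. from
#'   [extract_interface()]).
#' @param z_contact height of the contact plane, nm (default 0, the
#'   solid surface; use the first-layer top to read the angle there).
#' @param z_exclude drop points at or below this height, nm.
#' @param refine geometric (orthogonal-distance) refinement of the
#'   algebraic fit (default TRUE).
#' @return object of class `contact_angle` with `theta` (degrees),
#'   `center` (r0, z0), `radius`, `residual` (rms distance residual),
#'   `n_points`, `z_exclude`, `z_contact`.
#' @export
fit_contact_angle <- function(points, z_contact = 0, z_exclude = 0.8,
                              refine = TRUE) {
  pts <- points[points$z > z_exclude, , drop = FALSE]
  if (nrow(pts) < 5)
    stop("need at least 5 interface points above z_exclude; have ",
         nrow(pts))
  x <- pts$r; y <- pts$z
  A <- cbind(2 * x, 2 * y, 1)
  qrA <- qr(A)
  if (qrA$rank < 3)
    stop("interface points are collinear; circle fit is degenerate")
  sol <- qr.coef(qrA, x^2 + y^2)
  a <- sol[1]; b <- sol[2]
  R <- sqrt(sol[3] + a^2 + b^2)
  if (!is.finite(R) || R <= 0)
    stop("circle fit failed (non-positive radius)")
  if (refine) {
    obj <- function(p) sum((sqrt((x - p[1])^2 + (y - p[2])^2) - p[3])^2)
    opt <- stats::optim(c(a, b, R), obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (is.finite(opt$value) && opt$par[3] > 0) {
      a <- opt$par[1]; b <- opt$par[2]; R <- opt$par[3]
    }
  }
  resid <- sqrt(mean((sqrt((x - a)^2 + (y - b)^2) - R)^2))
  disc <- R^2 - (z_contact - b)^2
  if (disc <= 0)
    stop("fitted circle does not reach the contact plane z = ", z_contact)
  r_c <- a + sqrt(disc)               # contact line radius
  rad <- c(r_c - a, z_contact - b)    # radius vector at the contact point
  tang <- c(-rad[2], rad[1])          # tangent, oriented upward
  if (tang[2] < 0) tang <- -tang
  theta <- atan2(tang[2], -tang[1]) * 180 / pi
  if (!(theta > 0 && theta < 180))
    stop("extracted angle ", format(theta), " outside (0, 180) degrees")
  structure(list(theta = theta, center = c(r = a, z = b), radius = R,
                 residual = resid, n_points = nrow(pts),
                 z_exclude = z_exclude, z_contact = z_contact),
            class = "contact_angle")
}

#' @export
print.contact_angle <- function(x, ...) {
  cat(sprintf(paste0("contact_angle: theta = %.2f deg (R = %.3f nm, ",
                     "%d points, rms residual %.3g nm)\n"),
              x$theta, x$radius, x$n_points, x$residual))
  invisible(x)
}

#' Contact angle from droplet trajectory frames
#'
#' Convenience chain: [density_field()] -> [extract_interface()] ->
#' [fit_contact_angle()].
#'
#' @inheritParams density_field
#' @inheritParams extract_interface
#' @inheritParams fit_contact_angle
#' @return a `contact_angle`.
#' @export
contact_angle_from_frames <- function(frames, dr = 0.1, dz = 0.05,
                                      threshold_fraction = 0.5,
                                      z_exclude = 0.8, z_contact = 0,
                                      rho_bulk = NULL) {
  field <- density_field(frames, dr = dr, dz = dz)
  pts <- extract_interface(field, threshold_fraction, z_exclude, rho_bulk)
  fit_contact_angle(pts, z_contact = z_contact, z_exclude = z_exclude)
}

#' Contact-angle-based relative friction (Huang scaling)
#'
#' The wettability scaling lambda* proportional to (1 + cos theta)^2
#' predicts a relative friction (1 + cos theta_a)^2 / (1 + cos theta_b)^2
#' between two surfaces from their contact angles alone. It is monotone
#' decreasing in `theta_a` and vanishes as theta_a approaches 180
#' degrees.
#'
#' @param theta_a,theta_b contact angles in degrees, both in (0, 180).
#' @return dimensionless relative friction.
#' @examples
#' huang_relative_friction(68, 88)
#' @export
huang_relative_friction <- function(theta_a, theta_b) {
  if (any(c(theta_a, theta_b) <= 0) || any(c(theta_a, theta_b) >= 180))
    stop("contact angles must lie strictly between 0 and 180 degrees")
  (1 + cospi(theta_a / 180))^2 / (1 + cospi(theta_b / 180))^2
}
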
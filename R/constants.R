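#' Physical constants and unit conversions
#'
#' All lengths in the package are nanometres, energies kJ/mol, charges in
#' elementary charge units (e), times in picoseconds, temperatures in kelvin.
#' `gk_unit_factor()` is the single conversion used to express a Green-Kubo
#' friction coefficient computed in these internal units as N s/m^3.
#'
#' @details
#' The Green-Kubo integrand carries units (kJ mol^-1 nm^-1)^2 ps; dividing
#' by area (nm^2) and k_B T (kJ/mol) leaves (kJ/mol) ps nm^-4, and
#' \deqn{1\ \mathrm{kJ\,mol^{-1}\,ps\,nm^{-4}} = \frac{10^3}{N_A}
#'   \times 10^{-12} \times 10^{36}\ \mathrm{N\,s\,m^{-3}}
#'   \approx 1660.54\ \mathrm{N\,s\,m^{-3}}.}
#'
#' @return `gk_unit_factor()` returns the scalar conversion factor.
#' @export
gk_unit_factor <- function() {
  1e3 / .avogadro * 1e-12 / 1e-36
}

.avogadro <- 6.02214076e23

#' @rdname gk_unit_factor
#' @format `kB_kJmol`: Boltzmann constant in kJ mol^-1 K^-1.
#' @export
kB_kJmol <- 0.008314462618

#' @rdname gk_unit_factor
#' @format `ke_kJmol_nm`: Coulomb constant in kJ mol^-1 nm e^-2.
#' @export
ke_kJmol_nm <- 138.935458

# kJ mol^-1 nm^-1 expressed in newton, used by the SI round-trip contract
.force_unit_N <- 1e3 / .avogadro / 1e-9

#' Rigid three-site extended simple point charge (SPC/E) water model
#'
#' Parameters of the rigid three-site water used for all water-surface
#' energies: charges -0.8476 e (O) and +0.4238 e (H), O-H bond 0.1 nm,
#' H-O-H angle 109.47 degrees, and a single Lennard-Jones site on oxygen
#' (sigma 0.3166 nm, epsilon 0.650 kJ/mol).
#'
#' @return A list with elements `qO`, `qH`, `rOH` (nm), `angle` (degrees),
#'   `sigmaO` (nm), `epsilonO` (kJ/mol).
#' @examples
#' w <- spce_water()
#' w$qO + 2 * w$qH  # exactly neutral
#' @export
spce_water <- function() {
  list(qO = -0.8476, qH = 0.4238, rOH = 0.1, angle = 109.47,
       sigmaO = 0.3166, epsilonO = 0.650)
}

# canonical rigid water site matrix: rows O, H1, H2; dipole bisector along +z
.water_canonical <- function(model = spce_water()) {
  half <- model$angle / 2 * pi / 180
  rbind(O  = c(0, 0, 0),
        H1 = c( model$rOH * sin(half), 0, model$rOH * cos(half)),
        H2 = c(-model$rOH * sin(half), 0, model$rOH * cos(half)))
}

# rotation matrix taking unit z to unit vector u, then spinning by psi about u
.rot_to <- function(u, psi = 0) {
  u <- u / sqrt(sum(u^2))
  z <- c(0, 0, 1)
  c_ <- sum(z * u)
  if (c_ < -1 + 1e-12) {
    R1 <- diag(c(1, -1, -1))  # 180 degree flip about x
  } else {
    v <- c(z[2] * u[3] - z[3] * u[2],
           z[3] * u[1] - z[1] * u[3],
           z[1] * u[2] - z[2] * u[1])
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    R1 <- diag(3) + vx + vx %*% vx / (1 + c_)
  }
  cp <- cos(psi); sp <- sin(psi)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
               byrow = TRUE)
  Rspin <- diag(3) * cp + sp * ux + (1 - cp) * (u %o% u)
  Rspin %*% R1
}

#' Construct a rigid water configuration
#'
#' Places a rigid water with its oxygen at `o` and its dipole
#' bisector along `axis`, spun by `psi` radians about that axis.
#' `water_config()` instead takes explicit site positions and checks the
#' rigid geometry (O-H bond within 1e-6 nm, angle within 1e-4 degrees).
#'
#' @param o oxygen position, length-3 numeric, nm.
#' @param axis dipole bisector direction (need not be normalised).
#' @param psi spin angle about the axis, radians.
#' @param model water model parameter list, see [spce_water()].
#' @return A 3x3 numeric matrix with rows `O`, `H1`, `H2` of class
#'   `water_config`.
#' @export
place_water <- function(o, axis = c(0, 0, 1), psi = 0, model = spce_water()) {
  sites <- .water_canonical(model) %*% t(.rot_to(axis, psi))
  sites <- sweep(sites, 2, o, "+")
  rownames(sites) <- c("O", "H1", "H2")
  class(sites) <- c("water_config", class(sites))
  sites
}

#' @rdname place_water
#' @param h1,h2 hydrogen positions, nm.
#' @export
water_config <- function(o, h1, h2, model = spce_water()) {
  d1 <- sqrt(sum((h1 - o)^2)); d2 <- sqrt(sum((h2 - o)^2))
  if (abs(d1 - model$rOH) > 1e-6 || abs(d2 - model$rOH) > 1e-6)
    stop("O-H bond length deviates from the rigid geometry (",
         format(model$rOH), " nm)")
  ang <- acos(sum((h1 - o) * (h2 - o)) / (d1 * d2)) * 180 / pi
  if (abs(ang - model$angle) > 1e-4)
    stop("H-O-H angle ", format(ang), " deviates from rigid geometry")
  sites <- rbind(O = o, H1 = h1, H2 = h2)
  class(sites) <- c("water_config", class(sites))
  sites
}
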
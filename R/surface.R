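#' Periodic charged model surfaces
#'
#' A `surface` is a rigid planar lattice of atoms carrying partial charges
#' and Lennard-Jones parameters, periodic in x and y over a rectangular
#' cell. Three builders are provided: a graphene-like honeycomb sheet with
#' +q/-q pairs on para (diagonally opposite) vertices of each hexagon, a
#' square lattice with a +q/-q checkerboard, and a plane of rigid methylene
#' (CH2) groups with q_C = -2 q_H. Every builder guarantees exact overall
#' neutrality by integer bookkeeping of the +/- sites.
#'
#' @param atoms data frame with columns `label`, `x`, `y`, `z` (nm),
#'   `charge` (e), `epsilon` (kJ/mol), `sigma` (nm).
#' @param cell in-plane periodic cell lengths `c(Lx, Ly)`, nm.
#' @param z_plane height of the heavy-atom layer, nm.
#' @param kind one of `"hexagonal"`, `"square"`, `"ch2"`.
#' @param metadata free-form list recording the build parameters.
#' @return An object of class `surface`.
#' @seealso [build_hexagonal()], [build_square()], [build_ch2()]
#' @export
surface <- function(atoms, cell, z_plane = 0, kind = "custom",
                    metadata = list()) {
  s <- structure(list(atoms = atoms, cell = as.numeric(cell),
                      z_plane = z_plane, kind = kind, metadata = metadata),
                 class = "surface")
  validate_surface(s)
  s
}

#' @rdname surface
#' @param x a `surface`.
#' @export
validate_surface <- function(x) {
  a <- x$atoms
  stopifnot(is.data.frame(a),
            all(c("label", "x", "y", "z", "charge", "epsilon", "sigma")
                %in% names(a)))
  if (length(x$cell) != 2L || any(x$cell <= 0))
    stop("cell must be two positive in-plane lengths (nm)")
  if (any(a$epsilon < 0)) stop("lj epsilon must be >= 0")
  if (any(a$sigma <= 0)) stop("lj sigma must be > 0")
  if (any(abs(a$charge) > 1.0)) stop("|charge| exceeds 1.0 e")
  if (abs(sum(a$charge)) > 1e-10)
    stop("surface is not neutral: net charge ", format(sum(a$charge)), " e")
  if (any(a$x < -1e-9 | a$x > x$cell[1] + 1e-9 |
          a$y < -1e-9 | a$y > x$cell[2] + 1e-9))
    stop("atoms lie outside the periodic cell")
  # one atomic layer around z_plane; ch2 may carry an H layer above the C plane
  zspan <- if (identical(x$kind, "ch2")) 0.25 else 0.05
  if (any(abs(a$z - x$z_plane) > zspan + 1e-9))
    stop("atom z outside the surface layer")
  invisible(x)
}

#' @export
print.surface <- function(x, ...) {
  ch <- x$atoms$charge
  cat(sprintf("surface (%s): %d atoms, cell %.4f x %.4f nm\n",
              x$kind, nrow(x$atoms), x$cell[1], x$cell[2]))
  cat(sprintf("  charges: %d positive, %d negative, %d neutral; net %+.3g e\n",
              sum(ch > 0), sum(ch < 0), sum(ch == 0), sum(ch)))
  if (!is.null(x$metadata$q))
    cat(sprintf("  q = %.3f e, decoration '%s'\n", x$metadata$q,
                x$metadata$decoration %||% "none"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname surface
#' @export
cell_area <- function(x) prod(x$cell)

#' @rdname surface
#' @export
net_charge <- function(x) sum(x$atoms$charge)

#' Build a charged honeycomb (hexagonal-lattice) surface
#'
#' Tiles a rectangular 4-atom honeycomb unit cell (width sqrt(3)*a, height
#' 3*a for bond length a) `nx` by `ny` times. The default `"para"`
#' decoration places one +q and one -q atom per hexagon at para
#' (diagonally opposite) vertices, so charged sites form a periodic
#' sublattice with equal +/- counts; `"para-sparse"` decorates every other
#' hexagon in a checkerboard of hexagons and therefore needs even `nx` and
#' `ny` to tile. With the default bond length 0.142 nm, `nx = 26, ny = 16`
#' reproduces a 6.395 x 6.816 nm footprint.
#'
#' @param nx,ny repeat counts of the unit cell (>= 1).
#' @param q charge magnitude, e (>= 0).
#' @param bond_length nearest-neighbour bond, nm.
#' @param decoration charge pattern: `"para"`, `"para-sparse"` or `"none"`.
#' @param epsilon,sigma Lennard-Jones parameters of the solid atoms
#'   (defaults 0.2325 kJ/mol and 0.34 nm).
#' @param z_plane height of the atomic plane, nm.
#' @return A [surface].
#' @examples
#' s <- build_hexagonal(4, 4, q = 0.2)
#' net_charge(s)  # 0 exactly
#' @export
build_hexagonal <- function(nx, ny, q = 0, bond_length = 0.142,
                            decoration = c("para", "para-sparse", "none"),
                            epsilon = 0.2325, sigma = 0.34, z_plane = 0) {
  decoration <- match.arg(decoration)
  stopifnot(nx >= 1, ny >= 1, q >= 0)
  if (decoration == "para-sparse" && (nx %% 2L != 0L || ny %% 2L != 0L))
    stop("decoration 'para-sparse' tiles only for even nx and ny; got nx = ",
         nx, ", ny = ", ny)
  a <- bond_length
  ux <- sqrt(3) * a; uy <- 3 * a
  # 4-atom unit cell; atoms 1 and 4 are para vertices of one hexagon
  base <- rbind(c(0, 0), c(ux / 2, a / 2), c(ux / 2, 3 * a / 2), c(0, 2 * a))
  rows <- vector("list", nx * ny)
  k <- 0L
  for (j in seq_len(ny) - 1L) {
    for (i in seq_len(nx) - 1L) {
      qs <- c(0, 0, 0, 0)
      decorate <- switch(decoration,
                         "para" = TRUE,
                         "para-sparse" = (i + j) %% 2L == 0L,
                         "none" = FALSE)
      if (decorate && q > 0) qs <- c(q, 0, 0, -q)
      k <- k + 1L
      rows[[k]] <- data.frame(
        label = "CS",
        x = base[, 1] + i * ux, y = base[, 2] + j * uy, z = z_plane,
        charge = qs, epsilon = epsilon, sigma = sigma)
    }
  }
  atoms <- do.call(rbind, rows)
  surface(atoms, cell = c(nx * ux, ny * uy), z_plane = z_plane,
          kind = "hexagonal",
          metadata = list(q = q, bond_length = bond_length, nx = nx, ny = ny,
                          decoration = decoration))
}

#' Build a charged square-lattice surface
#'
#' Square lattice with lattice constant `lattice_constant`; the default
#' `"checkerboard"` decoration alternates +q and -q on nearest neighbours,
#' which tiles periodically only for even `nx` and `ny` (enforced whenever
#' q > 0 — an untileable combination raises an error rather than leaving a
#' silent charge imbalance). `"stripes"` alternates whole columns and needs
#' even `nx`.
#'
#' @inheritParams build_hexagonal
#' @param lattice_constant nearest-neighbour spacing, nm.
#' @param decoration `"checkerboard"`, `"stripes"` or `"none"`.
#' @return A [surface].
#' @export
build_square <- function(nx, ny, q = 0, lattice_constant = 0.25,
                         decoration = c("checkerboard", "stripes", "none"),
                         epsilon = 0.2325, sigma = 0.34, z_plane = 0) {
  decoration <- match.arg(decoration)
  stopifnot(nx >= 1, ny >= 1, q >= 0)
  if (q > 0) {
    if (decoration == "checkerboard" && (nx %% 2L != 0L || ny %% 2L != 0L))
      stop("checkerboard decoration tiles only for even nx and ny; got nx = ",
           nx, ", ny = ", ny)
    if (decoration == "stripes" && nx %% 2L != 0L)
      stop("stripes decoration tiles only for even nx; got nx = ", nx)
  }
  d <- lattice_constant
  g <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  qs <- rep(0, nrow(g))
  if (q > 0) {
    sign <- switch(decoration,
                   "checkerboard" = ifelse((g$i + g$j) %% 2L == 0L, 1, -1),
                   "stripes" = ifelse(g$i %% 2L == 0L, 1, -1),
                   "none" = 0)
    qs <- q * sign
  }
  atoms <- data.frame(label = "SQ", x = g$i * d, y = g$j * d, z = z_plane,
                      charge = qs, epsilon = epsilon, sigma = sigma)
  surface(atoms, cell = c(nx * d, ny * d), z_plane = z_plane, kind = "square",
          metadata = list(q = q, lattice_constant = lattice_constant,
                          nx = nx, ny = ny, decoration = decoration))
}

#' Build a plane of rigid methylene (CH2) groups
#'
#' Each group has one carbon in the `z_plane` and two hydrogens displaced
#' symmetrically toward the water side (C-H 0.109 nm, H-C-H 109.5
#' degrees); groups sit on a square lattice. The hydrogen charge `q_h`
#' (0 to 0.36 e) sets q_C = -2 q_h, so each group — and the surface — is
#' exactly neutral. Default LJ parameters follow a standard all-atom
#' alkane set (C: 0.276 kJ/mol, 0.35 nm; H: 0.1255 kJ/mol, 0.25 nm).
#'
#' @inheritParams build_hexagonal
#' @param q_h hydrogen partial charge, e, in [0, 0.36].
#' @param spacing square packing of the groups, nm.
#' @param ch_length C-H bond, nm.
#' @param hch_angle H-C-H angle, degrees.
#' @param lj list with numeric `C = c(epsilon, sigma)` and `H = c(epsilon,
#'   sigma)`.
#' @return A [surface].
#' @examples
#' s <- build_ch2(4, 4, q_h = 0.06)
#' range(s$atoms$charge)  # -0.12 (C) .. +0.06 (H)
#' @export
build_ch2 <- function(nx, ny, q_h = 0.06, spacing = 0.25, ch_length = 0.109,
                      hch_angle = 109.5,
                      lj = list(C = c(0.276, 0.35), H = c(0.1255, 0.25)),
                      z_plane = 0) {
  stopifnot(nx >= 1, ny >= 1)
  if (q_h < 0 || q_h > 0.36)
    stop("q_h must lie in [0, 0.36] e; got ", q_h)
  half <- hch_angle / 2 * pi / 180
  hz <- ch_length * cos(half)
  hx <- ch_length * sin(half)
  g <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  rows <- lapply(seq_len(nrow(g)), function(k) {
    cx <- g$i[k] * spacing; cy <- g$j[k] * spacing
    data.frame(
      label = c("C", "H1", "H2"),
      x = c(cx, cx + hx, cx - hx), y = cy,
      z = z_plane + c(0, hz, hz),
      charge = c(-2 * q_h, q_h, q_h),
      epsilon = c(lj$C[1], lj$H[1], lj$H[1]),
      sigma = c(lj$C[2], lj$H[2], lj$H[2]))
  })
  atoms <- do.call(rbind, rows)
  # wrap the H of edge groups back into the cell
  atoms$x <- atoms$x %% (nx * spacing)
  surface(atoms, cell = c(nx * spacing, ny * spacing), z_plane = z_plane,
          kind = "ch2",
          metadata = list(q_h = q_h, q = q_h, spacing = spacing,
                          ch_length = ch_length, hch_angle = hch_angle,
                          decoration = "ch2"))
}

#' Translate a surface in-plane and re-wrap into its periodic cell
#'
#' Used to exercise the periodicity invariants: translating by a lattice
#' vector yields the same atom multiset and hence identical energy maps.
#'
#' @param s a [surface].
#' @param shift length-2 in-plane translation, nm.
#' @return The translated [surface].
#' @export
translate_surface <- function(s, shift) {
  s$atoms$x <- (s$atoms$x + shift[1]) %% s$cell[1]
  s$atoms$y <- (s$atoms$y + shift[2]) %% s$cell[2]
  s
}
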
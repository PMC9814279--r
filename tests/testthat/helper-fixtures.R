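# shared tiny fixtures, built in code

# two-atom surface with hand-enterable geometry for brute-force oracles
two_atom_surface <- function(q = 0.2, cell = c(4, 4)) {
  surface(data.frame(label = c("A", "B"),
                     x = c(1.0, 2.0), y = c(1.0, 1.5), z = 0,
                     charge = c(q, -q), epsilon = 0.2325, sigma = 0.34),
          cell = cell, z_plane = 0, kind = "custom")
}

# a slab of waters at prescribed oxygen heights (upright orientation)
slab_frame <- function(zs, x = 0.5, y = 0.5) {
  lapply(zs, function(z) place_water(c(x, y, z)))
}

# independent brute-force water-surface energy: plain double loop,
# minimum image, shared cutoff; written without the package internals
brute_energy <- function(water, surf, cutoff = 1.0) {
  m <- spce_water()
  qs <- c(m$qO, m$qH, m$qH)
  lj <- 0; cb <- 0
  for (i in 1:3) {
    for (j in seq_len(nrow(surf$atoms))) {
      a <- surf$atoms[j, ]
      dx <- water[i, 1] - a$x; dx <- dx - surf$cell[1] * round(dx / surf$cell[1])
      dy <- water[i, 2] - a$y; dy <- dy - surf$cell[2] * round(dy / surf$cell[2])
      dz <- water[i, 3] - a$z
      r <- sqrt(dx^2 + dy^2 + dz^2)
      if (r > cutoff) next
      cb <- cb + 138.935458 * qs[i] * a$charge / r
      if (i == 1 && a$epsilon > 0) {
        sig <- (m$sigmaO + a$sigma) / 2
        eps <- sqrt(m$epsilonO * a$epsilon)
        lj <- lj + 4 * eps * ((sig / r)^12 - (sig / r)^6)
      }
    }
  }
  list(lj = unname(lj), coulomb = unname(cb), total = unname(lj + cb))
}
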
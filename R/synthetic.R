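#' Synthetic-data generators with known ground truth
#'
#' Every generator is deterministic given its `seed` (the global RNG
#' state is restored afterwards) and embeds its parameters in the output,
#' so each analysis operation can be closed-loop tested against the
#' generator's own truth.
#'
#' @name synthetic
NULL

.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Ornstein-Uhlenbeck tangential force series
#'
#' Stationary Gaussian process with autocovariance sigma2 * exp(-t/tau),
#' generated by the exact discrete AR(1) update, so the Green-Kubo
#' integral has the closed form sigma2 * tau * (1 - exp(-t_c/tau)) /
#' (A k_B T) — the analytic oracle for [friction_coefficient()].
#'
#' @param n number of samples.
#' @param dt sampling interval, ps (a warning is issued when dt >
#'   tau/10, where the discrete series resolves the correlation poorly).
#' @param tau correlation time, ps.
#' @param sigma2 force variance, (kJ mol^-1 nm^-1)^2.
#' @param area,temperature context carried on the series (defaults: the
#'   6.395 x 6.816 nm simulation footprint, 300 K).
#' @param n_components 1 (x only) or 2 (independent x and y).
#' @param seed RNG seed.
#' @return a [force_series()].
#' @export
gen_ou_force <- function(n, dt, tau, sigma2 = 25, area = 6.395 * 6.816,
                         temperature = 300, n_components = 1, seed = NULL) {
  stopifnot(n >= 2, dt > 0, tau > 0, sigma2 > 0)
  if (dt > tau / 10)
    warning("dt > tau/10: the discrete series undersamples the correlation")
  phi <- exp(-dt / tau)
  innov_sd <- sqrt(sigma2 * (1 - phi^2))
  v <- .with_seed(seed, {
    vapply(seq_len(n_components), function(j) {
      x0 <- stats::rnorm(1, 0, sqrt(sigma2))
      e <- stats::rnorm(n, 0, innov_sd)
      as.numeric(stats::filter(e, phi, method = "recursive", init = x0))
    }, numeric(n))
  })
  force_series(v, dt = dt, area = area, temperature = temperature,
               meta = list(generator = "ou", sigma2 = sigma2, tau = tau,
                           seed = seed))
}

#' Closed-form Green-Kubo friction of an OU force process
#'
#' @inheritParams gen_ou_force
#' @param t_cutoff upper integration limit, ps.
#' @return lambda in N s/m^3.
#' @export
ou_lambda_exact <- function(sigma2, tau, area, temperature, t_cutoff = 1.0) {
  sigma2 * tau * (1 - exp(-t_cutoff / tau)) /
    (area * kB_kJmol * temperature) * gk_unit_factor()
}

#' Spherical-cap droplet sampler with a smooth interface
#'
#' Samples molecule positions uniformly inside a spherical cap of contact
#' angle `theta_true` and sphere radius `R` sitting on the z = 0 plane,
#' with a tanh-smoothed boundary: a proposal at distance d from the
#' sphere centre is accepted with probability (1 - tanh((d - R)/width))/2,
#' emulating the finite liquid-vapor interfacial width of a simulated
#' droplet (default 0.3 nm). Optional Gaussian positional noise of
#' standard deviation `noise * R` models density noise. The default scale
#' (R = 2 nm, 50 frames of about 900 molecules each) mirrors a small
#' simulated sessile droplet.
#'
#' @param theta_true contact angle, degrees, in (0, 180).
#' @param R sphere radius, nm.
#' @param n_samples total molecule observations across all frames.
#' @param n_frames number of frames to split the samples into.
#' @param width tanh interface width, nm.
#' @param noise relative positional noise level (fraction of R).
#' @param seed RNG seed.
#' @return list of n x 3 position matrices (one per frame) with
#'   attributes `theta_true`, `R`, `width`, `noise`.
#' @export
gen_droplet <- function(theta_true, R = 2.0, n_samples = 45000,
                        n_frames = 50, width = 0.3, noise = 0,
                        seed = NULL) {
  stopifnot(theta_true > 0, theta_true < 180, R > 0, n_samples >= 1)
  z0 <- -R * cospi(theta_true / 180)  # sphere centre height
  half <- R + 4 * width
  ztop <- z0 + half
  pts <- .with_seed(seed, {
    out <- matrix(0, 0, 3)
    while (nrow(out) < n_samples) {
      m <- max(4L * (n_samples - nrow(out)), 1000L)
      p <- cbind(stats::runif(m, -half, half), stats::runif(m, -half, half),
                 stats::runif(m, 0, ztop))
      d <- sqrt(p[, 1]^2 + p[, 2]^2 + (p[, 3] - z0)^2)
      acc <- stats::runif(m) < (1 - tanh((d - R) / width)) / 2
      out <- rbind(out, p[acc, , drop = FALSE])
    }
    out <- out[seq_len(n_samples), , drop = FALSE]
    if (noise > 0) out <- out + stats::rnorm(length(out), 0, noise * R)
    out
  })
  idx <- rep(seq_len(n_frames), length.out = n_samples)
  frames <- lapply(split(seq_len(n_samples), idx), function(i)
    pts[i, , drop = FALSE])
  attributes(frames) <- c(attributes(frames),
                          list(theta_true = theta_true, R = R, width = width,
                               noise = noise, seed = seed))
  frames
}

#' Metropolis-sampled first-layer water over a surface
#'
#' Samples rigid single-molecule water poses within the first contact
#' layer (oxygen z in (z_plane, z_plane + thickness]) with Boltzmann
#' weights from the solid-water [pair_energy()] alone — water-water
#' interactions are deliberately omitted, so this exercises layer
#' selection, binning and Boltzmann consistency of the maps, not absolute
#' friction values. `n_molecules` independent chains are advanced
#' `n_sweeps` sweeps; one frame per sweep is recorded after `burn_in`.
#'
#' @param surface a [surface].
#' @param temperature K; `Inf` gives the uniform (always-accept) limit.
#' @param n_molecules independent chains per frame.
#' @param n_sweeps recorded sweeps.
#' @param burn_in discarded initial sweeps.
#' @param step_trans translation proposal s.d., nm.
#' @param step_rot rotation proposal half-width, radians.
#' @param thickness layer thickness, nm.
#' @param cutoff interaction cutoff, nm.
#' @param seed RNG seed.
#' @param model water parameters.
#' @return list of frames (each a list of `water_config`s) with
#'   attribute `acceptance_rate`; a warning is raised if any sweep
#'   accepts no move at all.
#' @export
gen_first_layer <- function(surface, temperature = 300, n_molecules = 16,
                            n_sweeps = 100, burn_in = 20, step_trans = 0.05,
                            step_rot = 0.6, thickness = 0.50, cutoff = 1.0,
                            seed = NULL, model = spce_water()) {
  stopifnot(temperature > 0, n_molecules >= 1, n_sweeps >= 1,
            step_trans > 0, step_rot > 0)
  beta <- 1 / (kB_kJmol * temperature)   # 0 in the T -> Inf limit
  zp <- surface$z_plane
  .with_seed(seed, {
    o <- cbind(stats::runif(n_molecules, 0, surface$cell[1]),
               stats::runif(n_molecules, 0, surface$cell[2]),
               zp + stats::runif(n_molecules, 0.5 * thickness, thickness))
    ax <- .rand_axes(n_molecules)
    psi <- stats::runif(n_molecules, 0, 2 * pi)
    energy <- vapply(seq_len(n_molecules), function(i)
      pair_energy(place_water(o[i, ], ax[i, ], psi[i], model), surface,
                  cutoff, model = model)$total, numeric(1))
    frames <- vector("list", n_sweeps)
    n_acc <- 0L; n_try <- 0L; dead_sweeps <- 0L
    for (sweep in seq_len(burn_in + n_sweeps)) {
      acc_sweep <- 0L
      for (i in seq_len(n_molecules)) {
        o_new <- o[i, ] + stats::rnorm(3, 0, step_trans)
        o_new[1] <- o_new[1] %% surface$cell[1]
        o_new[2] <- o_new[2] %% surface$cell[2]
        n_try <- n_try + 1L
        if (o_new[3] <= zp || o_new[3] > zp + thickness) next
        u <- .rand_axes(1)[1, ]
        rot_scale <- stats::runif(1, -step_rot, step_rot)
        ax_new <- ax[i, ] + rot_scale * u
        ax_new <- ax_new / sqrt(sum(ax_new^2))
        psi_new <- (psi[i] + stats::runif(1, -step_rot, step_rot)) %% (2 * pi)
        e_new <- pair_energy(place_water(o_new, ax_new, psi_new, model),
                             surface, cutoff, model = model)$total
        if (stats::runif(1) < exp(-beta * (e_new - energy[i]))) {
          o[i, ] <- o_new; ax[i, ] <- ax_new; psi[i] <- psi_new
          energy[i] <- e_new
          n_acc <- n_acc + 1L; acc_sweep <- acc_sweep + 1L
        }
      }
      if (acc_sweep == 0L) dead_sweeps <- dead_sweeps + 1L
      if (sweep > burn_in)
        frames[[sweep - burn_in]] <- lapply(seq_len(n_molecules), function(i)
          place_water(o[i, ], ax[i, ], psi[i], model))
    }
    if (dead_sweeps > 0L)
      warning(dead_sweeps, " sweep(s) accepted no move")
    attr(frames, "acceptance_rate") <- n_acc / n_try
    attr(frames, "temperature") <- temperature
    frames
  })
}

.rand_axes <- function(n) {
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u / sqrt(rowSums(u^2))
}

#' Synthetic lambda versus corrugation dataset
#'
#' Records lambda_i = zeta_true * var_E_i * (1 + eps_i) with Gaussian
#' relative noise, the closed-loop oracle for [fit_zeta()].
#'
#' @param var_E corrugation variances, (kJ/mol)^2 (default: 12 values in
#'   the linear regime below the 0.45 kJ/mol cutoff).
#' @param zeta_true true slope, N s m^-3 per (kJ/mol)^2.
#' @param noise relative noise level (e.g. 0.05 for 5 percent).
#' @param q optional charge magnitudes attached to the records.
#' @param seed RNG seed.
#' @return data frame with columns `surface`, `q`, `var_E`, `lambda`,
#'   `kind` and attribute `zeta_true`.
#' @export
gen_lambda_dataset <- function(var_E = seq(0.01, 0.19, length.out = 12),
                               zeta_true = 130, noise = 0.05, q = NA,
                               seed = NULL) {
  stopifnot(all(var_E >= 0))
  eps <- .with_seed(seed, stats::rnorm(length(var_E), 0, noise))
  d <- data.frame(surface = paste0("synthetic-", seq_along(var_E)),
                  q = rep_len(q, length(var_E)), var_E = var_E,
                  lambda = zeta_true * var_E * (1 + eps),
                  kind = "synthetic")
  attr(d, "zeta_true") <- zeta_true
  d
}
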
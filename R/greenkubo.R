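#' Tangential force series on a surface
#'
#' Uniformly sampled total tangential force acting on the solid surface,
#' with the area and temperature context required by the Green-Kubo
#' relation. One or two in-plane components may be supplied (columns of
#' `values`).
#'
#' @param values numeric vector (one component) or matrix with one column
#'   per component, kJ mol^-1 nm^-1.
#' @param dt sampling interval, ps.
#' @param area surface area A, nm^2.
#' @param temperature temperature T, K.
#' @param meta optional provenance list.
#' @return object of class `force_series`.
#' @export
force_series <- function(values, dt, area, temperature, meta = list()) {
  v <- as.matrix(values)
  stopifnot(dt > 0, area > 0, temperature > 0)
  if (nrow(v) < 2) stop("force series needs at least 2 samples")
  if (ncol(v) > 2) stop("at most two in-plane components")
  structure(list(values = v, dt = dt, area = area,
                 temperature = temperature, meta = meta),
            class = "force_series")
}

#' @export
print.force_series <- function(x, ...) {
  cat(sprintf(paste0("force_series: %d samples x %d component(s), dt = %g ps",
                     " (%.4g ps total)\n  A = %.4g nm^2, T = %g K\n"),
              nrow(x$values), ncol(x$values), x$dt, (nrow(x$values) - 1) * x$dt,
              x$area, x$temperature))
  invisible(x)
}

#' @rdname force_series
#' @param path CSV with columns `time_ps` and one or two force columns.
#' @export
read_force_csv <- function(path, area, temperature) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2) stop("force CSV needs time_ps plus >= 1 force column")
  dt <- stats::median(diff(d[[1]]))
  force_series(as.matrix(d[, -1, drop = FALSE]), dt, area, temperature,
               meta = list(source = path))
}

#' Stationary autocorrelation of a force series
#'
#' Mean-subtracted autocorrelation with biased (1/N) normalisation by
#' default, so the estimate is integrable; the spectral (FFT) and direct
#' O(N^2) estimators are algebraically identical and agree to round-off.
#' Any nonzero mean (a drift the equilibrium average should not have) is
#' removed and recorded.
#'
#' @param series a [force_series()].
#' @param max_lag largest lag, ps; must be shorter than the series.
#' @param method `"fft"` (default) or `"direct"` (brute-force oracle).
#' @param normalization `"biased"` (1/N) or `"unbiased"` (1/(N-k)).
#' @param demean subtract the sample mean first (default TRUE).
#' @return object of class `force_acf` with `lags` (ps) and `values`
#'   (matrix, one column per force component, units (kJ mol^-1 nm^-1)^2).
#' @export
autocorrelation <- function(series, max_lag, method = c("fft", "direct"),
                            normalization = c("biased", "unbiased"),
                            demean = TRUE) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  v <- series$values
  n <- nrow(v)
  duration <- (n - 1) * series$dt
  if (max_lag >= duration)
    stop("max_lag (", max_lag, " ps) must be below the series duration (",
         duration, " ps)")
  nlag <- floor(max_lag / series$dt)
  means <- colMeans(v)
  if (demean) v <- sweep(v, 2, means)
  vals <- vapply(seq_len(ncol(v)), function(j) {
    x <- v[, j]
    if (method == "fft") {
      m <- stats::nextn(2L * n)
      xp <- c(x, rep(0, m - n))
      s <- Re(stats::fft(Mod(stats::fft(xp))^2, inverse = TRUE)) / m
      raw <- s[seq_len(nlag + 1L)]
    } else {
      raw <- vapply(0:nlag, function(k)
        sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]), numeric(1))
    }
    if (normalization == "biased") raw / n else raw / (n - (0:nlag))
  }, numeric(nlag + 1L))
  force_acf(lags = (0:nlag) * series$dt, values = vals,
            flavor = paste(method, normalization),
            area = series$area, temperature = series$temperature,
            drift = means)
}

#' @rdname autocorrelation
#' @param lags lag times, ps (starting at 0).
#' @param values ACF values; vector or matrix (one column per component).
#' @param flavor estimator description.
#' @param area,temperature context carried to [friction_coefficient()].
#' @param drift removed series means.
#' @export
force_acf <- function(lags, values, flavor = "analytic", area = NULL,
                      temperature = NULL, drift = NULL) {
  values <- as.matrix(values)
  stopifnot(length(lags) == nrow(values), lags[1] == 0)
  if (any(values[1, ] < 0)) stop("ACF at lag 0 must be non-negative")
  structure(list(lags = lags, values = values, flavor = flavor,
                 area = area, temperature = temperature, drift = drift),
            class = "force_acf")
}

#' Green-Kubo friction coefficient from a force autocorrelation
#'
#' Implements the Green-Kubo estimate lambda = 1/(A k_B T) *
#' integral_0^t_c <F(t)F(0)> dt by trapezoidal quadrature of the ACF up to
#' `t_cutoff` (default 1 ps, the interval over which the running integral
#' has plateaued for these interfaces), converted to N s/m^3 via
#' [gk_unit_factor()]. When the ACF has two components the reported lambda
#' is their average. The running integral is returned for plateau
#' inspection, and a simple convergence flag compares the last fifth of
#' the running integral with its final value.
#'
#' @param acf a `force_acf` (or a [force_series()], which is
#'   autocorrelated first with `max_lag = t_cutoff`).
#' @param area surface area, nm^2 (taken from the ACF context if missing).
#' @param temperature temperature, K.
#' @param t_cutoff upper integration limit, ps.
#' @return object of class `friction_result` with `lambda` (N s/m^3),
#'   `running` (data frame `t_ps`, `lambda`), `t_cutoff`, `converged`,
#'   `lambda_components`.
#' @export
friction_coefficient <- function(acf, area = NULL, temperature = NULL,
                                 t_cutoff = 1.0) {
  if (inherits(acf, "force_series")) {
    if (is.null(area)) area <- acf$area
    if (is.null(temperature)) temperature <- acf$temperature
    acf <- autocorrelation(acf, max_lag = t_cutoff)
  }
  stopifnot(inherits(acf, "force_acf"))
  area <- area %||% acf$area
  temperature <- temperature %||% acf$temperature
  if (is.null(area) || is.null(temperature))
    stop("area and temperature must be supplied (or carried by the ACF)")
  if (t_cutoff > max(acf$lags) + 1e-12)
    stop("t_cutoff (", t_cutoff, " ps) exceeds the ACF range (",
         max(acf$lags), " ps)")
  keep <- acf$lags <= t_cutoff + 1e-12
  lags <- acf$lags[keep]
  vals <- acf$values[keep, , drop = FALSE]
  dt <- diff(lags)
  scale <- gk_unit_factor() / (area * kB_kJmol * temperature)
  run <- apply(vals, 2, function(y)
    c(0, cumsum(dt * (y[-length(y)] + y[-1]) / 2)) * scale)
  lam_comp <- run[nrow(run), ]
  lambda <- mean(lam_comp)
  run_mean <- rowMeans(run)
  tail_idx <- lags >= 0.8 * t_cutoff
  converged <- if (lambda == 0) TRUE else {
    max(abs(run_mean[tail_idx] - lambda)) <= 0.05 * abs(lambda)
  }
  structure(list(lambda = lambda, lambda_components = lam_comp,
                 running = data.frame(t_ps = lags, lambda = run_mean),
                 t_cutoff = t_cutoff, converged = converged,
                 area = area, temperature = temperature,
                 note = if (ncol(vals) == 2)
                   "lambda is the x/y component average" else
                     "single-component lambda"),
            class = "friction_result")
}

#' @export
print.friction_result <- function(x, ...) {
  cat(sprintf("friction_result: lambda = %.4g N s/m^3 (t_cutoff = %g ps)\n",
              x$lambda, x$t_cutoff))
  cat(sprintf("  %s; running integral %s\n", x$note,
              if (x$converged) "plateaued" else "NOT converged"))
  invisible(x)
}

#' Relative friction coefficient
#'
#' Ratio lambda_q / lambda_0 of a charged-surface friction coefficient to
#' the neutral-surface one.
#'
#' @param lambda_q,lambda_0 friction coefficients (numbers or
#'   `friction_result`s), same units.
#' @return dimensionless ratio.
#' @examples
#' relative_friction(4.9e5, 1.2e4)  # about 41
#' @export
relative_friction <- function(lambda_q, lambda_0) {
  lq <- if (inherits(lambda_q, "friction_result")) lambda_q$lambda else lambda_q
  l0 <- if (inherits(lambda_0, "friction_result")) lambda_0$lambda else lambda_0
  if (l0 <= 0) stop("reference friction lambda_0 must be positive")
  lq / l0
}
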
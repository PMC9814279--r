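#' Fit the linear friction-corrugation relationship lambda = zeta (dE)^2
#'
#' Least-squares slope of the friction coefficient on the energy-map
#' variance, through the origin by default (the Coulomb corrugation — and
#' with it the Green-Kubo lambda — vanishes as the map flattens). Records
#' with a corrugation sqrt(var_E) at or above `cutoff` (default 0.45
#' kJ/mol, where the linear regime ends) are excluded and reported.
#' zeta is reported in N s m^-3 per (kJ/mol)^2; the fitted value is only
#' comparable across datasets under this unit convention.
#'
#' @param data data frame with columns `var_E` ((kJ/mol)^2) and `lambda`
#'   (N s/m^3); see [gen_lambda_dataset()].
#' @param through_origin force a zero intercept (default TRUE).
#' @param cutoff admissibility cutoff on sqrt(var_E), kJ/mol.
#' @param weights optional per-record weights.
#' @return object of class `zeta_fit` with `zeta`, `intercept`,
#'   `r_squared`, `n_used`, `excluded` (row indices), `cutoff`.
#' @examples
#' d <- data.frame(var_E = c(0.01, 0.05, 0.1), lambda = 130 * c(0.01, 0.05, 0.1))
#' fit_zeta(d)$zeta  # 130
#' @export
fit_zeta <- function(data, through_origin = TRUE, cutoff = 0.45,
                     weights = NULL) {
  stopifnot(all(c("var_E", "lambda") %in% names(data)))
  if (any(data$var_E < 0)) stop("var_E must be >= 0")
  adm <- sqrt(data$var_E) < cutoff
  if (!any(adm))
    stop("all records exceed the corrugation cutoff sqrt(var_E) < ",
         cutoff, " kJ/mol")
  need <- if (through_origin) 1L else 2L
  if (sum(adm) < need)
    stop("need at least ", need, " admissible records; have ", sum(adm))
  d <- data[adm, , drop = FALSE]
  w <- if (is.null(weights)) NULL else weights[adm]
  fit <- if (through_origin)
    stats::lm(lambda ~ 0 + var_E, data = d, weights = w)
  else
    stats::lm(lambda ~ var_E, data = d, weights = w)
  co <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- if (through_origin) sum(d$lambda^2) else
    sum((d$lambda - mean(d$lambda))^2)
  structure(list(zeta = unname(co[["var_E"]]),
                 intercept = if (through_origin) 0 else unname(co[[1]]),
                 r_squared = if (tss > 0) 1 - rss / tss else 1,
                 n_used = sum(adm), excluded = which(!adm), cutoff = cutoff,
                 through_origin = through_origin, fit = fit,
                 units = "N s m^-3 per (kJ/mol)^2"),
            class = "zeta_fit")
}

#' @export
print.zeta_fit <- function(x, ...) {
  cat(sprintf("zeta_fit: zeta = %.4g %s (R^2 = %.4f, n = %d%s)\n",
              x$zeta, x$units, x$r_squared, x$n_used,
              if (length(x$excluded))
                sprintf(", %d excluded above cutoff", length(x$excluded))
              else ""))
  invisible(x)
}

#' Charge-scaling exponent of corrugation or friction
#'
#' Log-log regression exponent of `var_E` (or `lambda`) against the
#' charge magnitude q; the Coulomb-only corrugation scales exactly as
#' q^2, so the exponent is a sharp diagnostic of the quadratic law.
#' Records with q = 0 cannot enter a log-log fit and are skipped with a
#' warning.
#'
#' @param data data frame with a `q` column and the field to regress.
#' @param field `"var_E"` or `"lambda"`.
#' @return list of class `q_scaling` with `exponent`, `se`, `n`.
#' @export
q_scaling_exponent <- function(data, field = c("var_E", "lambda")) {
  field <- match.arg(field)
  stopifnot(all(c("q", field) %in% names(data)))
  if (any(data$q == 0)) {
    warning("skipping ", sum(data$q == 0), " record(s) with q = 0")
    data <- data[data$q > 0, , drop = FALSE]
  }
  if (length(unique(data$q)) < 3)
    stop("need at least 3 distinct q > 0 values")
  y <- data[[field]]
  if (any(y <= 0)) stop(field, " must be positive for a log-log fit")
  fit <- stats::lm(log(y) ~ log(q), data = data)
  lx <- log(data$q)
  s2 <- sum(stats::residuals(fit)^2) / max(nrow(data) - 2, 1)
  se <- sqrt(s2 / sum((lx - mean(lx))^2))
  structure(list(exponent = unname(stats::coef(fit)[2]),
                 se = se, n = nrow(data), field = field),
            class = "q_scaling")
}

#' @export
print.q_scaling <- function(x, ...) {
  cat(sprintf("q_scaling: %s ~ q^%.4f (se %.2g, n = %d)\n",
              x$field, x$exponent, x$se, x$n))
  invisible(x)
}
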
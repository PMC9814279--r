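test_that("ACF of a constant series is identically zero after demeaning", {
  fs <- force_series(rep(3.7, 100), dt = 0.1, area = 10, temperature = 300)
  a <- autocorrelation(fs, max_lag = 2)
  expect_true(all(abs(a$values) < 1e-12))
})

test_that("white-noise ACF is the variance at lag 0 and noise elsewhere", {
  set.seed(5)
  x <- rnorm(200000, sd = 3)
  fs <- force_series(x, dt = 0.01, area = 10, temperature = 300)
  a <- autocorrelation(fs, max_lag = 0.2)
  expect_equal(a$values[1], 9, tolerance = 0.02)
  expect_true(max(abs(a$values[-1])) < 9 * 0.02)
})

test_that("spectral and direct ACF estimators agree to round-off", {
  for (n in c(513, 4096)) {
    fs <- gen_ou_force(n = n, dt = 0.01, tau = 0.3, sigma2 = 9, seed = n)
    a1 <- autocorrelation(fs, max_lag = 2, method = "fft")
    a2 <- autocorrelation(fs, max_lag = 2, method = "direct")
    expect_lt(max(abs(a1$values - a2$values)), 1e-10)
    u1 <- autocorrelation(fs, max_lag = 2, method = "fft",
                          normalization = "unbiased")
    u2 <- autocorrelation(fs, max_lag = 2, method = "direct",
                          normalization = "unbiased")
    expect_lt(max(abs(u1$values - u2$values)), 1e-10)
  }
})

test_that("lag bounds are validated", {
  fs <- force_series(rnorm(100), dt = 0.1, area = 10, temperature = 300)
  expect_error(autocorrelation(fs, max_lag = 9.9), "duration")
  a <- autocorrelation(fs, max_lag = 5)
  expect_error(friction_coefficient(a, 10, 300, t_cutoff = 6), "exceeds")
})

test_that("zero force gives zero friction", {
  fs <- force_series(rep(0, 1000), dt = 0.01, area = 43.59,
                     temperature = 300)
  expect_equal(friction_coefficient(fs, t_cutoff = 1)$lambda, 0)
})

test_that("an analytic exponential ACF integrates to the closed form", {
  sigma2 <- 25; tau <- 0.2; A <- 43.59; T_ <- 300
  lags <- seq(0, 1, by = tau / 100)
  a <- force_acf(lags, sigma2 * exp(-lags / tau))
  for (tc in c(0.5, 1.0)) {
    fr <- friction_coefficient(a, A, T_, t_cutoff = tc)
    expect_equal(fr$lambda, ou_lambda_exact(sigma2, tau, A, T_, tc),
                 tolerance = 0.005)
  }
  # running integral is monotone for a positive ACF and flagged converged
  fr <- friction_coefficient(a, A, T_, t_cutoff = 1.0)
  expect_true(all(diff(fr$running$lambda) >= 0))
  expect_true(fr$converged)
  expect_equal(fr$running$lambda[1], 0)
})

test_that("a non-decaying ACF is flagged as non-convergent", {
  lags <- seq(0, 1, by = 0.01)
  a <- force_acf(lags, rep(4, length(lags)))
  expect_false(friction_coefficient(a, 10, 300, t_cutoff = 1)$converged)
})

test_that("friction estimates from many OU seeds agree with the closed form", {
  lam <- sapply(1:20, function(s) {
    fs <- gen_ou_force(n = 1e6, dt = 0.01, tau = 1.0, sigma2 = 25,
                       n_components = 2, seed = s)
    friction_coefficient(fs, t_cutoff = 1.0)$lambda
  })
  exact <- ou_lambda_exact(25, 1.0, 6.395 * 6.816, 300, 1.0)
  expect_equal(mean(lam) / exact, 1, tolerance = 0.02)
})

test_that("x and y components of an isotropic force process agree", {
  fs <- gen_ou_force(n = 1e6, dt = 0.01, tau = 1.0, sigma2 = 25,
                     n_components = 2, seed = 9)
  fr <- friction_coefficient(fs, t_cutoff = 1.0)
  expect_equal(fr$lambda_components[1], fr$lambda_components[2],
               tolerance = 0.12)
  expect_equal(fr$lambda, mean(fr$lambda_components))
})

test_that("internal-unit lambda equals an explicit SI computation", {
  # closed-loop unit contract: convert the ACF to SI by hand and integrate
  sigma2 <- 16; tau <- 0.4; A <- 20; T_ <- 350
  lags <- seq(0, 1, by = 0.002)
  acf_int <- force_acf(lags, sigma2 * exp(-lags / tau))
  lam_pkg <- friction_coefficient(acf_int, A, T_, t_cutoff = 1)$lambda
  f_N <- 1e3 / 6.02214076e23 / 1e-9        # kJ/mol/nm -> N
  acf_si <- sigma2 * exp(-lags / tau) * f_N^2           # N^2
  dt_si <- 0.002e-12                                     # s
  integral <- sum((acf_si[-1] + acf_si[-length(acf_si)]) / 2 * dt_si)
  lam_si <- integral / (A * 1e-18 * 1.380649e-23 * T_)   # N s / m^3
  expect_equal(lam_pkg, lam_si, tolerance = 1e-6)
})

test_that("relative friction is plain division with validation", {
  expect_equal(relative_friction(5, 5), 1)
  expect_equal(relative_friction(8.2, 2), 4.1)
  expect_error(relative_friction(1, 0), "positive")
  expect_error(relative_friction(1, -2), "positive")
  # the two printed friction coefficients span a factor of about 41
  expect_equal(relative_friction(4.9e5, 1.2e4), 40.83, tolerance = 1e-3)
})

test_that("force CSV round trip feeds the friction chain", {
  fs <- gen_ou_force(n = 5000, dt = 0.01, tau = 0.5, sigma2 = 4, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(time_ps = (seq_len(5000) - 1) * 0.01, Fx = fs$values[, 1])
  write.csv(d, path, row.names = FALSE)
  back <- read_force_csv(path, area = fs$area, temperature = 300)
  expect_equal(back$dt, 0.01)
  expect_equal(back$values[, 1], fs$values[, 1], tolerance = 1e-8)
})
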
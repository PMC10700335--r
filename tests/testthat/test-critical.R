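test_that("power-law fits recover noiseless exponents to 1e-6", {
  lam_c <- 0.09
  lam <- lam_c + seq(0.002, 0.05, length.out = 10)
  scan <- data.frame(lam = lam, rho_s = 2 * (lam - lam_c)^0.276)
  fb <- fit_beta(scan, lam_c, window = c(0, 0.05))
  expect_lt(abs(fb$exponent - 0.276), 1e-6)
  expect_lt(abs(fb$amplitude - 2), 1e-6)

  t <- 10:2000
  fd <- fit_delta(data.frame(t = t, rho = 1.3 * t^-0.1595),
                  window = c(10, 2000))
  expect_lt(abs(fd$exponent - 0.1595), 1e-6)

  # constant density has zero decay exponent
  fc <- fit_delta(data.frame(t = t, rho = rep(0.25, length(t))),
                  window = c(10, 2000))
  expect_lt(abs(fc$exponent), 1e-12)
})

test_that("power-law fits refuse under-determined inputs", {
  scan <- data.frame(lam = c(0.1, 0.11), rho_s = c(0.05, 0.08))
  expect_error(fit_beta(scan, 0.09), "at least 4")
  expect_error(fit_delta(data.frame(t = c(10, 20, 30), rho = c(1, .5, .3)),
                         window = c(10, 30)),
               "at least 4")
})

test_that("order-parameter variance matches the closed form", {
  expect_equal(variance_chi(rep(0.3, 10), 100), 0)
  expect_equal(variance_chi(rep(c(0, 1), 50), 100), 25)  # N p (1-p)
  set.seed(2)
  x <- runif(1000)
  expect_gte(variance_chi(x, 500), 0)
  expect_equal(variance_chi(x, 500), 500 * mean((x - mean(x))^2))
  expect_error(variance_chi(0.5, 100))
})

test_that("pseudo-critical location is exact on a parabola and guarded at edges", {
  lam <- seq(0.20, 0.28, by = 0.01)
  curve <- data.frame(lam = lam, chi = 5 - 300 * (lam - 0.23)^2)
  expect_lt(abs(locate_pseudo_critical(curve) - 0.23), 1e-9)

  # vertex off the grid nodes
  curve2 <- data.frame(lam = lam, chi = 5 - 300 * (lam - 0.2345)^2)
  expect_lt(abs(locate_pseudo_critical(curve2) - 0.2345), 1e-9)

  mono <- data.frame(lam = lam, chi = lam)
  expect_warning(pk <- locate_pseudo_critical(mono), "boundary")
  expect_equal(pk, max(lam))
  expect_error(locate_pseudo_critical(data.frame(lam = 1:3, chi = 1:3)),
               "5")

  # noisy parabola: mean recovered peak within the noise level
  set.seed(4)
  pks <- replicate(10, {
    noisy <- data.frame(lam = lam, chi = 5 - 300 * (lam - 0.23)^2 +
                          rnorm(length(lam), sd = 0.05))
    suppressWarnings(locate_pseudo_critical(noisy))
  })
  expect_lt(abs(mean(pks) - 0.23), 0.005)
})

test_that("finite-size extrapolation is exact on linear inputs and guarded", {
  pts <- data.frame(N = c(500, 1000, 2000, 4000),
                    lambda_N = 0.24 + 0.5 / c(500, 1000, 2000, 4000))
  fs <- extrapolate_lambda_c2(pts)
  expect_equal(fs$lambda_c2, 0.24, tolerance = 1e-12)
  expect_equal(fs$slope_a, 0.5, tolerance = 1e-9)
  expect_error(extrapolate_lambda_c2(pts[1:2, ]), "3 distinct")
  expect_error(extrapolate_lambda_c2(data.frame(N = c(500, 500, 500),
                                                lambda_N = c(.2, .21, .22))),
               "3 distinct")
})

test_that("mode counting separates bimodal from unimodal synthetic histograms", {
  expect_identical(count_modes(c(0, 0, 10, 0, 0)), 1L)       # point mass
  expect_identical(count_modes(rep(4, 20)), 1L)              # uniform plateau
  set.seed(10)
  for (rep in 1:50) {
    w <- 100
    n1 <- sample(5:20, 1)
    n2 <- sample(60:90, 1)
    size <- sample(c(2000, 5000, 10000), 1)
    x1 <- rbinom(size, w, n1 / w)
    x2 <- rbinom(size, w, n2 / w)
    bimodal <- tabulate(c(x1, x2) + 1L, nbins = w + 1)
    unimodal <- tabulate(x1 + 1L, nbins = w + 1)
    expect_identical(count_modes(bimodal, smoothing = 2L), 2L)
    expect_identical(count_modes(unimodal, smoothing = 2L), 1L)
  }
})

test_that("onset estimation brackets a synthetic transition", {
  lam <- seq(0.05, 0.15, by = 0.005)
  scan <- data.frame(lam = lam, rho_s = pmax(0, lam - 0.09)^0.276)
  est <- estimate_lambda_c1(scan)
  expect_lte(abs(est$lambda_c1 - 0.09), 0.0025 + 1e-9)  # grid resolution
  expect_equal(est$bracket, c(0.09, 0.095))

  # power-law linearity criterion lands near the true onset too
  est2 <- estimate_lambda_c1(scan, method = "powerlaw")
  expect_lt(abs(est2$lambda_c1 - 0.09), 0.0025)

  expect_error(estimate_lambda_c1(data.frame(lam = lam, rho_s = 0)),
               "bracket")
  expect_error(estimate_lambda_c1(data.frame(lam = lam, rho_s = 1)),
               "bracket")
})
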
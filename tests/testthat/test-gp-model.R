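test_that("GP parameters satisfy their defining identities", {
  p <- gp_params(0.25, 100)
  m <- 1 / (1 - 0.25)
  expect_equal(p$m, m)
  expect_equal(p$lambda2, 1 - sqrt(m))
  expect_equal(p$lambda1, 0.25 * 100 * sqrt(m))
  # GP mean and variance in terms of (b, k, m)
  expect_equal(p$lambda1 / (1 - p$lambda2), 0.25 * 100)
  expect_equal(p$lambda1 / (1 - p$lambda2)^3, 0.25 * 100 / m)
  expect_error(gp_params(1.2, 10), "coverage")
  expect_error(gp_params(0.5, 2.5), "positive integer")
  expect_warning(gp_params(0.8, 10), "validity range")
})

test_that("mean-to-variance ratio is 1/(1-b) with the documented domain", {
  expect_equal(mean_variance_ratio(0.5), 2)
  expect_equal(mean_variance_ratio(0.25), 4 / 3)
  # small-coverage limit m ~ 1 + b
  for (b in c(1e-4, 1e-3, 1e-2))
    expect_equal(mean_variance_ratio(b), 1 + b, tolerance = 2 * b)
  expect_error(mean_variance_ratio(0), "coverage")
  expect_error(mean_variance_ratio(1), "coverage")
  expect_warning(mean_variance_ratio(0.8), "validity range")
})

test_that("GP pmf reduces to the Poisson at m = 1", {
  p <- gp_params(0.5, 10, m = 1)
  expect_equal(p$lambda2, 0)
  xs <- 0:50
  expect_equal(gp_pmf(xs, p), dpois(xs, 5), tolerance = 1e-12)
  expect_equal(gp_pmf(5, p), dpois(5, 5))
})

test_that("GP pmf matches its closed form and truncation convention", {
  p <- gp_params(0.25, 40)
  expect_equal(gp_pmf(0, p), exp(-p$lambda1))
  # frozen high-precision value of the pmf at b = 0.25, k = 100, m = 4/3
  p100 <- gp_params(0.25, 100)
  expect_equal(gp_pmf(25, p100), 0.091825194873682261, tolerance = 1e-13)
  expect_equal(gp_pmf(10, p100), 9.2023635891955356e-5, tolerance = 1e-13)
  expect_equal(gp_pmf(0, p100), 2.904010606817678e-13, tolerance = 1e-13)
  # underdispersion zeroes the mass where lambda1 + x*lambda2 <= 0
  plow <- gp_params(0.5, 2)  # lambda1 ~ 1.41, lambda2 ~ -0.41
  xs <- 0:20
  pm <- gp_pmf(xs, plow)
  theta <- plow$lambda1 + xs * plow$lambda2
  expect_true(all(pm[theta <= 0] == 0))
  expect_true(all(pm >= 0 & pm <= 1))
  expect_error(gp_pmf(-1, p), "non-negative")
  expect_error(gp_pmf(2.5, p), "non-negative")
})

test_that("exact posterior normalizes, concentrates near x/b, and controls truncation", {
  for (x in c(0, 1, 10, 100)) for (b in c(0.1, 0.5)) {
    pp <- posterior_pmf(x, b)
    expect_equal(sum(pp$prob), 1, tolerance = 1e-12)
    expect_true(all(pp$prob >= 0))
    expect_equal(min(pp$k), max(x, 1))
    expect_lt(pp$truncation_mass_bound, 1e-10)
    mode <- pp$k[which.max(pp$prob)]
    expect_gte(mode, x / b - 2)
  }
  expect_error(posterior_pmf(10, 0.25, tol = -1), "positive")
  expect_error(posterior_pmf(2.5, 0.25), "non-negative integer")
  expect_warning(posterior_pmf(10, 0.8), "validity range")
})

test_that("gamma posterior moments match their closed forms", {
  g <- posterior_gamma(0, 0.5)
  expect_equal(g$mu, 1.5)
  expect_equal(round(g$sigma2, 4), 1.7778)
  g <- posterior_gamma(100, 0.25)
  expect_equal(round(g$mu, 4), 403.6667)
  expect_equal(g$sigma2, 101 / (0.25 * 1.25)^2) # = 1034.24
  # algebraic identities shape*scale = mu, shape*scale^2 = sigma2
  gs <- posterior_gamma(c(0, 3, 17, 400), 0.3)
  expect_equal(gs$shape * gs$scale, gs$mu)
  expect_equal(gs$shape * gs$scale^2, gs$sigma2)
  expect_true(all(gs$mu > 0 & gs$sigma2 > 0))
  expect_error(posterior_gamma(10, 1.5), "between 0 and 1")
})

test_that("gamma posterior mean is monotone in x and in coverage", {
  xs <- 0:200
  mus <- posterior_gamma(xs, 0.25)$mu
  expect_true(all(diff(mus) > 0))
  bs <- seq(0.05, 0.95, by = 0.05)
  mus <- vapply(bs, function(b) posterior_gamma(50, b)$mu, numeric(1))
  expect_true(all(diff(mus) < 0))
})

test_that("posterior percentiles invert the gamma CDF", {
  g <- posterior_gamma(100, 0.25)
  # frozen values from an independent quantile implementation
  expect_equal(posterior_percentile(g, 0.005), 325.64335816371937,
               tolerance = 1e-10)
  expect_equal(posterior_percentile(g, 0.995), 491.30826941720926,
               tolerance = 1e-10)
  qs <- posterior_percentile(g, c(0.1, 0.25, 0.5, 0.9))
  expect_true(all(diff(qs) > 0))
  # right skew: median below mean
  expect_lt(posterior_percentile(g, 0.5), g$mu)
  # round trip through the CDF
  for (q in c(0.005, 0.31, 0.995))
    expect_equal(pgamma(posterior_percentile(g, q), shape = g$shape,
                        scale = g$scale), q, tolerance = 1e-9)
  expect_error(posterior_percentile(g, 0), "between 0 and 1")
  expect_error(posterior_percentile(g, 1), "between 0 and 1")
})

test_that("gamma approximation tracks the exact posterior away from tiny counts", {
  # thresholds fixed from the exact computation: the moment formulas are a
  # large-x calibration, so x >= 5 is the supported comparison regime
  for (x in c(5, 10, 50, 100, 500)) for (b in c(0.1, 0.25, 0.5)) {
    pp <- posterior_pmf(x, b)
    g <- posterior_gamma(x, b)
    expect_lt(rel_err(g$mu, pp$mean), 0.05)
    expect_lt(tvd_gamma_vs_exact(x, b), 0.10)
  }
  # and the agreement tightens as x grows
  expect_lt(tvd_gamma_vs_exact(500, 0.25), 0.04)
  expect_lt(rel_err(posterior_gamma(500, 0.25)$mu, posterior_pmf(500, 0.25)$mean),
            5e-4)
})

test_that("simulated GP moments tie the count model to the sampler", {
  set.seed(1)
  N <- 3e6
  for (b in c(0.1, 0.5)) for (k in c(500, 5000)) {
    x <- sample_observed_count(k, round(b * N), N, n = 4000)
    m <- 1 / (1 - b)
    expect_equal(mean(x), b * k, tolerance = 0.03)
    expect_equal(var(x), b * k / m, tolerance = 0.15)
  }
})
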
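test_that("mean size by duration aggregates and conserves totals", {
  av <- data.frame(size = c(2, 4, 9), duration = c(1L, 1L, 3L))
  cur <- mean_size_by_duration(av)
  expect_equal(cur$duration, c(1L, 3L))
  expect_equal(cur$mean_size, c(3, 9))
  expect_equal(cur$n, c(2L, 1L))
  expect_equal(sum(cur$n * cur$mean_size), sum(av$size))
  expect_equal(nrow(mean_size_by_duration(av[0, ])), 0)
})

test_that("double power-law fitter recovers known parameters", {
  d <- unique(round(exp(seq(log(1), log(1e4), length.out = 60))))
  s <- double_powerlaw(d, C = 1, sigma1 = 2, sigma2 = 1, Phi = 100)
  fit <- fit_double_powerlaw(data.frame(duration = d, mean_size = s))
  expect_true(fit$converged)
  expect_equal(fit$sigma1, 2, tolerance = 0.01)
  expect_equal(fit$sigma2, 1, tolerance = 0.01)
  expect_equal(fit$Phi, 100, tolerance = 0.01)
  expect_equal(fit$C, 1, tolerance = 0.01)
  # under 5% multiplicative lognormal noise, parameters within 5%
  set.seed(21)
  for (i in 1:5) {
    sn <- s * exp(rnorm(length(s), 0, 0.05))
    fn <- fit_double_powerlaw(data.frame(duration = d, mean_size = sn))
    expect_equal(fn$sigma1, 2, tolerance = 0.05)
    expect_equal(fn$sigma2, 1, tolerance = 0.05)
    expect_equal(fn$Phi, 100, tolerance = 0.35)
  }
})

test_that("pure power laws are fitted with an unidentifiable transition", {
  d <- unique(round(exp(seq(log(1), log(1e3), length.out = 40))))
  s <- 2 * d^1.5
  fit <- fit_double_powerlaw(data.frame(duration = d, mean_size = s))
  expect_equal(fit$sigma1, 1.5, tolerance = 0.02)
  expect_equal(fit$sigma2, 1.5, tolerance = 0.02)
  expect_false(fit$phi_identifiable)
})

test_that("degenerate curves are flagged instead of fitted silently", {
  cur <- data.frame(duration = 1:3, mean_size = c(2, 4, 8))
  fit <- fit_double_powerlaw(cur)
  expect_false(fit$converged)
  expect_true(fit$low_confidence)
})

test_that("truncated MLE recovers exponents from an inverse-CDF oracle", {
  set.seed(22)
  x <- rtruncpow(1e5, 1.5, 100, 1e4)
  est <- fit_truncated_powerlaw(x, 100, 1e4)
  expect_equal(est$exponent, 1.5, tolerance = 0.034)
  expect_false(est$low_confidence)
  # likelihood scale invariance: duplicating the sample leaves the MLE fixed
  est2 <- fit_truncated_powerlaw(c(x, x), 100, 1e4)
  expect_equal(est2$exponent, est$exponent, tolerance = 1e-6)
})

test_that("truncated MLE is calibrated across exponents", {
  set.seed(23)
  for (a in c(1.2, 1.5, 2.0)) {
    x <- rtruncpow(1e4, a, 50, 5e3)
    est <- fit_truncated_powerlaw(x, 50, 5e3)
    expect_lt(abs(est$exponent - a), 2 * est$se + 0.02)
  }
  # continuous variant agrees on real-valued data
  set.seed(24)
  u <- runif(2e4)
  xc <- (100^(-0.5) - u * (100^(-0.5) - 1e4^(-0.5)))^(-2)  # a = 1.5 cont.
  estc <- fit_truncated_powerlaw(xc, 100, 1e4)
  expect_false(estc$discrete)
  expect_equal(estc$exponent, 1.5, tolerance = 0.05)
})

test_that("binned regression cross-checks the MLE", {
  set.seed(25)
  x <- rtruncpow(5e4, 1.5, 100, 1e4)
  expect_equal(fit_powerlaw_binned(x, 100, 1e4)$exponent, 1.5,
               tolerance = 0.12)
})

test_that("crackling prediction handles the alpha singularity", {
  expect_equal(crackling_prediction(1.5, 2)$chi_cn, 2)
  expect_equal(crackling_prediction(2, 2)$chi_cn, 1)
  sing <- crackling_prediction(1.0, 2)
  expect_true(sing$singular)
  expect_true(is.na(sing$chi_cn))
  expect_true(crackling_prediction(1.015, 2)$singular)
  expect_false(crackling_prediction(1.05, 2)$singular)
})

test_that("exponent suite enforces the 20-generation validity rule", {
  set.seed(26)
  av <- data.frame(size = rpois(500, 20) + 1,
                   duration = sample(1:10, 500, TRUE))
  class(av) <- c("avalanche_set", "data.frame")
  es <- exponent_suite(av)
  expect_false(es$valid)
  expect_true(is.na(es$chi))
  expect_true(is.na(es$alpha))
})

test_that("uncorrelated unit-rate events scale linearly (chi near 1)", {
  # avalanches built from independent events: size = duration
  set.seed(27)
  durs <- rtruncpow(2e4, 2, 1, 300)
  av <- data.frame(size = vapply(durs, function(d) sum(rpois(d, 1)) + d,
                                 numeric(1)),
                   duration = as.integer(durs))
  class(av) <- c("avalanche_set", "data.frame")
  es <- exponent_suite(av)
  expect_true(es$valid)
  expect_equal(es$chi, 1, tolerance = 0.1)
})

test_that("first4 mode estimates chi from the first four generations", {
  d <- 1:40
  s <- 3 * d^1.8
  av <- data.frame(size = rep(s, each = 3), duration = rep(d, each = 3))
  class(av) <- c("avalanche_set", "data.frame")
  es <- exponent_suite(av, mode = "first4")
  expect_equal(es$chi, 1.8, tolerance = 0.01)
})

test_that("rescue map masks unobservable cells and matches direct calls", {
  sim <- crit_frac_sim()
  m <- rescue_map(sim, f = 1e-3, k_grid = c(1, 4),
                  theta_grid = c(100, 3000), consolidate = TRUE)
  # theta = 100 * f = 0.1 spikes: below the one-spike resolution
  expect_true(all(m$unobservable[m$theta == 100]))
  expect_true(all(!m$unobservable[m$theta == 3000]))
  # a 1x1 grid equals the direct pipeline + suite call
  m1 <- rescue_map(sim, f = 1, k_grid = 2, theta_grid = 100)
  av <- avalanche_pipeline(sim, f = 1, k = 2, theta = 100)
  es <- exponent_suite(av)
  expect_equal(m1$chi, es$chi)
  expect_equal(m1$alpha, es$alpha)
  expect_error(rescue_map(sim, k_grid = c(2, 1), theta_grid = 1),
               "strictly increasing")
})
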
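test_that("parameter constructor applies the critical-balance weight rule", {
  p <- make_params(g = 3.5, N = 1e6, Gamma = 1, f_E = 0.8)
  expect_equal(p$J, 1e-5)
  expect_equal(p$sigma, 1)
  # same J, subcritical balance: sigma = 10 * (0.8 - 0.2 * 3.75)
  expect_equal(mean_field_sigma(p, 3.75), 0.5)
  expect_equal(make_params(g = 3.75)$sigma, 0.5)
  expect_equal(p$N_E, 8e5)
  expect_equal(p$N_I, 2e5)
})

test_that("invalid parameters are rejected", {
  expect_error(make_params(N = 0), "N must")
  expect_error(make_params(f_E = 1.2), "f_E")
  expect_error(make_params(f_E = 0), "f_E")
  expect_error(make_params(lambda_drive = -1), "lambda_drive")
  expect_error(make_params(g = -1), "non-negative")
  expect_error(simulate_network(make_params(N = 1e4), steps = 10,
                                sample_fractions = 2),
               "fractions")
  expect_error(simulate_network(make_params(N = 1e4), steps = 10,
                                sample_fractions = 1e-6),
               "fewer than one")
  expect_error(simulate_raster(make_params(N = 100), M = 200, steps = 10),
               "M must not exceed N")
})

test_that("quiescent state is absorbing without drive and drive is calibrated", {
  p0 <- make_params(g = 3.5, lambda_drive = 0)
  set.seed(1)
  expect_identical(unname(step_counts(0, 0, p0)), c(0L, 0L, 0L))
  sim <- simulate_network(p0, steps = 100, seed = 1)
  expect_true(all(activity(sim$runs[[1]]) == 0))
  # with drive but no coupling, activity is pure drive: mean = N * lambda
  pj <- make_params(g = 3.5, J = 1e-300)
  sim <- simulate_network(pj, steps = 5e4, seed = 2)
  a <- activity(sim$runs[[1]])
  expect_equal(mean(a), 20, tolerance = 3 * sd(a) / sqrt(length(a)) / 20)
})

test_that("refractory exhaustion empties the next step", {
  p <- make_params(N = 1e4, g = 3.5, lambda_drive = 0)
  set.seed(3)
  out <- step_counts(p$N_E, p$N_I, p)
  expect_identical(unname(out[1:2]), c(0L, 0L))
})

test_that("count-form update matches the explicit per-neuron oracle", {
  p <- make_params(N = 100, g = 3.5, lambda_drive = 2e-3)
  # identical starting state: 10 E and 3 I neurons just fired
  fired <- c(rep(TRUE, 10), rep(FALSE, p$N_E - 10),
             rep(TRUE, 3), rep(FALSE, p$N_I - 3))
  set.seed(42)
  reps <- 5e3
  a_count <- replicate(reps, sum(step_counts(10, 3, p)[1:2]))
  a_oracle <- replicate(reps, sum(oracle_step_perneuron(fired, p)))
  ks <- suppressWarnings(stats::ks.test(a_count, a_oracle))
  expect_gt(ks$p.value, 0.01)
  # and over whole trajectories: stationary activity distribution agrees
  set.seed(43)
  sim <- simulate_network(p, steps = 4e3)
  a1 <- activity(sim$runs[[1]])
  a2 <- oracle_simulate_perneuron(p, 4e3)
  ks2 <- suppressWarnings(stats::ks.test(a1, a2))
  expect_gt(ks2$p.value, 0.01)
})

test_that("refractoriness bounds successive counts in every class", {
  sim <- simulate_network(make_params(N = 1e4, g = 3.4,
                                      lambda_drive = 1e-3),
                          steps = 2000, seed = 5)
  nE <- sim$runs[[1]]$nE
  nI <- sim$runs[[1]]$nI
  expect_true(all(nE[-1] + nE[-length(nE)] <= 8e3))
  expect_true(all(nI[-1] + nI[-length(nI)] <= 2e3))
})

test_that("coupled subsampling is consistent with the population trace", {
  sim <- simulate_network(make_params(N = 1e4, g = 3.45, lambda_drive = 1e-4),
                          steps = 5000, sample_fractions = c(0.05, 1),
                          seed = 6)
  run <- sim$runs[[1]]
  a <- activity(run)
  expect_identical(run$sampled[["1"]], a)          # full sampling is exact
  s <- run$sampled[["0.05"]]
  expect_true(all(s <= a))
  expect_true(all(s <= 500))
  # unbiasedness: sampled mean close to f * population mean
  expect_equal(mean(s), 0.05 * mean(a), tolerance = 0.05)
})

test_that("tracked rasters respect refractoriness and match their counts", {
  p <- make_params(N = 1e4, g = 3.45, lambda_drive = 1e-3)
  rast <- simulate_raster(p, M = 50, steps = 3000, seed = 7)
  m <- raster_matrix(rast)
  expect_identical(unname(colSums(m)), as.numeric(rast$counts))
  # no neuron fires in two consecutive steps
  expect_true(all(m[, -1] + m[, -ncol(m)] <= 1))
  # stratified composition
  expect_equal(rast$M_E, 40)
})

test_that("empirical branching ratio tracks the mean-field value and flags", {
  p <- make_params(N = 1e5, g = 3.5, lambda_drive = 2e-4)
  expect_false(branching_ratio(rep(0, 100), p)$defined)
  sim <- simulate_network(p, steps = 5e4, seed = 8)
  br <- branching_ratio(sim$runs[[1]], p, floor = 1000, ceiling = 4000)
  expect_true(br$defined)
  expect_equal(br$sigma, 1, tolerance = 0.1)
})

test_that("empirical branching ratio is non-increasing in g", {
  set.seed(9)
  sig <- vapply(c(3.0, 3.5, 3.6, 3.75), function(g) {
    p <- make_params(N = 1e5, g = g, lambda_drive = 1e-4)
    sim <- simulate_network(p, steps = 2e4)
    branching_ratio(sim$runs[[1]], p, floor = 100, ceiling = 5000)$sigma
  }, numeric(1))
  expect_true(all(diff(sig) < 0.05))
})
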
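test_that("coarse-graining sums windows and drops the remainder", {
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5), 2), c(3, 7))
  x <- rpois(103, 4)
  expect_identical(coarse_grain(x, 1), x)
  for (k in c(2, 5, 10)) {
    cg <- coarse_grain(x, k)
    expect_length(cg, length(x) %/% k)
    expect_equal(sum(cg), sum(x[seq_len(k * (length(x) %/% k))]))
  }
  expect_error(coarse_grain(x, 0), "k must")
  expect_error(coarse_grain(x, 2.5), "k must")
})

test_that("thresholding zeroes strictly-below bins and keeps the rest", {
  expect_equal(apply_threshold(c(0, 3, 5, 0, 2), 3), c(0, 3, 5, 0, 0))
  x <- c(4, 1, 0, 9)
  expect_equal(apply_threshold(x, 0), x)
  expect_equal(apply_threshold(x, max(x) + 1), rep(0, 4))
  expect_error(apply_threshold(x, -1), "non-negative")
})

test_that("avalanche extraction matches a brute-force oracle", {
  av <- extract_avalanches(c(0, 3, 5, 0, 0, 4, 0))
  expect_equal(av$size, c(8, 4))
  expect_equal(av$duration, c(2L, 1L))
  expect_equal(nrow(extract_avalanches(rep(0, 10))), 0)
  # property: agreement with explicit scanning on random series, including
  # series that start or end inside an avalanche
  set.seed(11)
  for (i in 1:25) {
    x <- ifelse(runif(60) < 0.4, 0, rpois(60, 8))
    got <- extract_avalanches(x)
    want <- oracle_avalanches(x)
    expect_equal(got$size, want$size)
    expect_equal(got$duration, want$duration)
    expect_equal(sum(got$size), sum(x))
  }
})

test_that("exclusive size convention subtracts the threshold baseline", {
  x <- c(0, 5, 7, 0)
  inc <- extract_avalanches(x)
  exc <- extract_avalanches(x, size_convention = "exclusive", theta = 4)
  expect_equal(inc$size, 12)
  expect_equal(exc$size, 12 - 4 * 2)
})

test_that("pipeline composes, pools runs and respects boundaries", {
  x <- c(0, 1, 0, 0, 1, 0)
  av <- avalanche_pipeline(x, k = 1, theta = 1)
  expect_equal(av$size, c(1, 1))
  expect_equal(av$duration, c(1L, 1L))
  # runs never merge across boundaries: two runs each ending/starting hot
  runs <- list(c(0, 2, 3), c(4, 1, 0))
  av2 <- avalanche_pipeline(runs, k = 1, theta = 1)
  expect_equal(nrow(av2), 2)
  expect_equal(sort(av2$size), c(5, 5))
  expect_equal(av2$run_id, c(1L, 2L))
  # pooled count equals sum of per-run counts
  n_pooled <- nrow(av2)
  n_each <- sum(vapply(runs, function(r)
    nrow(avalanche_pipeline(r, k = 1, theta = 1)), numeric(1)))
  expect_equal(n_pooled, n_each)
})

test_that("total suprathreshold activity is non-increasing in the threshold", {
  # the avalanche *count* itself is not monotone (raising theta can split a
  # long avalanche in two, e.g. c(5, 1, 5) at theta = 3), but the total
  # retained activity and the longest duration both shrink monotonically
  set.seed(12)
  for (i in 1:10) {
    x <- ifelse(runif(200) < 0.5, 0, rpois(200, 10))
    stats <- vapply(c(0, 1, 3, 6, 10, 15), function(th) {
      av <- avalanche_pipeline(x, theta = th)
      c(sum(av$size), max(c(av$duration, 0L)))
    }, numeric(2))
    expect_true(all(diff(stats[1, ]) <= 0))
    expect_true(all(diff(stats[2, ]) <= 0))
  }
})

test_that("avalanches at a higher threshold nest inside lower-threshold ones", {
  # interval nesting, checked against explicit interval arithmetic
  intervals <- function(x, th) {
    y <- apply_threshold(x, th)
    r <- rle(y != 0)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    cbind(s[r$values], e[r$values])
  }
  set.seed(13)
  for (i in 1:20) {
    x <- ifelse(runif(100) < 0.4, 0, rpois(100, 6))
    lo <- intervals(x, 2)
    hi <- intervals(x, 7)
    if (nrow(hi) == 0) next
    nested <- apply(hi, 1, function(iv)
      any(lo[, 1] <= iv[1] & lo[, 2] >= iv[2]))
    expect_true(all(nested))
  }
})

test_that("coarse-graining can only merge or preserve suprathreshold epochs", {
  set.seed(14)
  for (i in 1:10) {
    x <- ifelse(runif(240) < 0.5, 0, rpois(240, 5))
    n1 <- nrow(avalanche_pipeline(x, k = 1, theta = 0))
    for (k in c(2, 4, 8)) {
      nk <- nrow(avalanche_pipeline(x, k = k, theta = 0))
      expect_lte(nk, n1)
    }
  }
})

test_that("fractional thresholds on integer spike data are unobservable", {
  x <- c(0L, 3L, 0L, 1L)
  av <- avalanche_pipeline(x, theta = 0.4)
  expect_true(attr(av, "unobservable"))
  expect_equal(nrow(av), 0)
  # real-valued spike densities accept fractional thresholds
  av2 <- avalanche_pipeline(c(0, 0.6, 0, 0.2), theta = 0.4)
  expect_false(attr(av2, "unobservable"))
  expect_equal(nrow(av2), 1)
})
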
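#' Rescale a threshold for a sampling fraction
#'
#' The threshold-subsampling equivalence rescales a fully sampled threshold
#' `theta100` to a fraction-`f` threshold `theta100 * f^xi`.  On integer
#' spike data the result is rounded to the nearest integer with a minimum
#' of 1; values below 0.5 before rounding fall under the model's one-spike
#' resolution and are flagged unobservable.
#'
#' @param theta100 threshold on the fully sampled scale (`>= 1`).
#' @param f sampling fraction in `(0, 1]`.
#' @param xi collapse exponent (`>= 0`).
#' @return List with `theta` (integer, `NA` if unobservable), `raw`
#'   (unrounded value) and `unobservable`.
#' @examples
#' rescaled_threshold(3000, 0.001, 1)$theta  # 3
#' @export
rescaled_threshold <- function(theta100, f, xi) {
  if (theta100 < 1) stop("theta100 must be >= 1")
  if (f <= 0 || f > 1) stop("f must lie in (0, 1]")
  if (xi < 0) stop("xi must be non-negative")
  raw <- theta100 * f^xi
  if (raw < 0.5)
    return(list(theta = NA_real_, raw = raw, unobservable = TRUE))
  list(theta = max(1, round(raw)), raw = raw, unobservable = FALSE)
}

#' Collapse error of a family of chi-versus-k curves
#'
#' Quantifies how well \eqn{\chi(k)} curves measured at different sampling
#' fractions collapse onto each other: the mean, over `theta100` groups and
#' shared valid `k` points with at least two curves, of the across-fraction
#' population variance of \eqn{\chi}, normalized by the squared range of
#' the pooled \eqn{\chi} values (dimensionless; 0 for identical curves).
#'
#' @param family list of curves; each curve is a list with fields `f`,
#'   `theta100`, `k` (shared grid), `chi` (numeric, `NA` where invalid).
#' @return List with `error` (`NA` if fewer than two comparable curves),
#'   `n_points` (number of (theta100, k) cells compared) and `defined`.
#' @examples
#' fam <- list(list(f = 1,   theta100 = 100, k = 1:3, chi = c(1, 1, 1)),
#'             list(f = 0.1, theta100 = 100, k = 1:3, chi = c(2, 2, 2)))
#' collapse_error(fam)$error  # var(1,2)/range^2 = 0.25
#' @export
collapse_error <- function(family) {
  if (length(family) < 2)
    return(list(error = NA_real_, n_points = 0L, defined = FALSE))
  pooled <- unlist(lapply(family, function(cv) cv$chi[is.finite(cv$chi)]))
  if (length(pooled) < 2)
    return(list(error = NA_real_, n_points = 0L, defined = FALSE))
  rng <- diff(range(pooled))
  vars <- c()
  for (th in unique(vapply(family, `[[`, numeric(1), "theta100"))) {
    group <- Filter(function(cv) cv$theta100 == th, family)
    if (length(group) < 2) next
    kg <- group[[1]]$k
    for (i in seq_along(kg)) {
      vals <- vapply(group, function(cv) cv$chi[i], numeric(1))
      vals <- vals[is.finite(vals)]
      if (length(vals) >= 2) {
        # population variance (divide by n), per the collapse-cost definition
        vars <- c(vars, mean((vals - mean(vals))^2))
      }
    }
  }
  if (!length(vars))
    return(list(error = NA_real_, n_points = 0L, defined = FALSE))
  err <- if (rng == 0) 0 else mean(vars) / rng^2
  list(error = err, n_points = length(vars), defined = TRUE)
}

#' Scan the collapse exponent
#'
#' For each candidate collapse exponent `xi` on a grid, builds the family
#' of \eqn{\chi(k)} curves with thresholds `theta100 * f^xi` (rounded per
#' [rescaled_threshold()]) across sampling fractions and `theta100` values,
#' computes the total collapse error, and returns the error profile and its
#' minimizer `xi_star`.  \eqn{\chi(k)} evaluations are cached by
#' `(f, theta)` so the scan cost grows with the number of distinct
#' rescaled thresholds, not grid size.
#'
#' @param x an `"ei_simulation"` (with coupled sampled traces for every
#'   requested fraction) or any input accepted by [avalanche_pipeline()].
#' @param fractions at least two sampling fractions.
#' @param theta100_set thresholds on the fully sampled scale.
#' @param xi_grid candidate exponents (default `seq(0, 2, by = 0.1)`).
#' @param k_grid coarse-graining grid shared by all curves.
#' @param mode passed to [exponent_suite()].
#' @return Object of class `"collapse_scan"`: list with `profile` (data
#'   frame `xi`, `error`, `n_points`, `defined`), `xi_star`, and the scan
#'   settings.
#' @export
scan_collapse <- function(x, fractions, theta100_set = c(100, 1000, 10000),
                          xi_grid = seq(0, 2, by = 0.1),
                          k_grid = 2^(0:6), mode = "full") {
  if (length(fractions) < 2)
    stop("need at least two sampling fractions for a collapse scan")
  # enumerate the distinct (f, theta) cells needed across the whole scan,
  # then compute chi(k) per cell with one coarse-graining pass per (f, k)
  needed <- new.env(parent = emptyenv())
  for (xi in xi_grid) for (th100 in theta100_set) for (f in fractions) {
    rt <- rescaled_threshold(th100, f, xi)
    if (!rt$unobservable)
      assign(paste(f, rt$theta, sep = "|"), c(f, rt$theta), envir = needed)
  }
  cells <- as.list(needed)
  cell_f <- vapply(cells, `[`, numeric(1), 1)
  chi_tab <- new.env(parent = emptyenv())
  for (f in unique(cell_f)) {
    thetas <- sort(unique(vapply(cells[cell_f == f], `[`, numeric(1), 2)))
    series <- pipeline_series(x, f)
    for (ki in seq_along(k_grid)) {
      k <- k_grid[ki]
      cg <- lapply(series, coarse_grain, k = k)
      for (theta in thetas) {
        av <- do.call(rbind, lapply(cg, function(s)
          extract_avalanches(apply_threshold(s, theta))))
        class(av) <- c("avalanche_set", "data.frame")
        es <- exponent_suite(av, mode = mode)
        key <- paste(f, theta, sep = "|")
        cur <- chi_tab[[key]]
        if (is.null(cur)) cur <- rep(NA_real_, length(k_grid))
        cur[ki] <- if (es$valid && is.finite(es$chi)) es$chi else NA_real_
        chi_tab[[key]] <- cur
      }
    }
  }
  chi_curve <- function(f, theta) chi_tab[[paste(f, theta, sep = "|")]]
  rows <- lapply(xi_grid, function(xi) {
    family <- list()
    for (th100 in theta100_set) {
      for (f in fractions) {
        rt <- rescaled_threshold(th100, f, xi)
        if (rt$unobservable) next
        family[[length(family) + 1]] <- list(
          f = f, theta100 = th100, k = k_grid,
          chi = chi_curve(f, rt$theta))
      }
    }
    ce <- collapse_error(family)
    data.frame(xi = xi, error = ce$error, n_points = ce$n_points,
               defined = ce$defined)
  })
  profile <- do.call(rbind, rows)
  ok <- profile$defined & is.finite(profile$error)
  xi_star <- if (any(ok)) profile$xi[ok][which.min(profile$error[ok])] else NA_real_
  structure(list(profile = profile, xi_star = xi_star,
                 fractions = fractions, theta100_set = theta100_set,
                 k_grid = k_grid),
            class = "collapse_scan")
}

#' @export
print.collapse_scan <- function(x, ...) {
  cat(sprintf("Collapse scan over xi in [%g, %g]: xi* = %g\n",
              min(x$profile$xi), max(x$profile$xi), x$xi_star))
  invisible(x)
}
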
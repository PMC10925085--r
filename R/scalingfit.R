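#' Mean avalanche size as a function of duration
#'
#' Groups an avalanche set by duration and returns the mean size and the
#' number of avalanches per duration; durations with no avalanches are
#' omitted.
#'
#' @param av an avalanche set (data frame with `size`, `duration`).
#' @return Data frame with columns `duration`, `mean_size`, `n`
#'   (durations strictly increasing); zero rows if `av` is empty.
#' @export
mean_size_by_duration <- function(av) {
  if (!nrow(av))
    return(data.frame(duration = integer(0), mean_size = numeric(0),
                      n = integer(0)))
  agg <- tapply(av$size, av$duration, mean)
  cnt <- tapply(av$size, av$duration, length)
  d <- as.integer(names(agg))
  o <- order(d)
  data.frame(duration = d[o], mean_size = as.numeric(agg)[o],
             n = as.integer(cnt)[o])
}

#' Double power-law fit of the mean size-duration curve
#'
#' Fits, in log space with equal weight per duration point, the curve
#' \deqn{S(d) = C d^{\sigma_1} [1 + (d/\Phi)^\gamma]^{(\sigma_2-\sigma_1)/\gamma}}
#' whose local slope is \eqn{\sigma_1} for \eqn{d \ll \Phi} and
#' \eqn{\sigma_2} for \eqn{d \gg \Phi}; \eqn{\gamma} governs the abruptness
#' of the transition and is held fixed (default 4).  \eqn{\sigma_1} is the
#' scaling exponent \eqn{\chi} of short avalanches and \eqn{\sigma_2} the
#' trivial long-duration slope \eqn{\chi_{lg}}.
#'
#' Optimization uses Levenberg-Marquardt least squares with multiple starts
#' (first-decade slope for \eqn{\sigma_1}, last-decade slope for
#' \eqn{\sigma_2}, and a set of transition-point candidates for
#' \eqn{\Phi}); ties are broken by lowest residual, then smallest
#' \eqn{\Phi}.  When the two slopes are indistinguishable the transition
#' point is unidentifiable and flagged.
#'
#' @param curve data frame from [mean_size_by_duration()] (columns
#'   `duration`, `mean_size`).
#' @param gamma transition sharpness (fixed during the fit; default 4).
#' @return Object of class `"double_powerlaw_fit"`: list with `C`,
#'   `sigma1`, `sigma2`, `Phi`, `gamma`, `chi` (= `sigma1`), `chi_lg`
#'   (= `sigma2`), `residual` (mean squared log-residual), `converged`,
#'   `low_confidence`, `phi_identifiable`.
#' @export
fit_double_powerlaw <- function(curve, gamma = 4) {
  d <- curve$duration
  s <- curve$mean_size
  keep <- is.finite(d) & is.finite(s) & d > 0 & s > 0
  d <- as.numeric(d[keep]); s <- s[keep]
  n <- length(d)
  low_conf <- n < 4 || (max(d) / min(d)) < 10
  empty_fit <- function() {
    structure(list(C = NA_real_, sigma1 = NA_real_, sigma2 = NA_real_,
                   Phi = NA_real_, gamma = gamma, chi = NA_real_,
                   chi_lg = NA_real_, residual = NA_real_,
                   converged = FALSE, low_confidence = TRUE,
                   phi_identifiable = FALSE, n_points = n),
              class = "double_powerlaw_fit")
  }
  if (n < 4) return(empty_fit())

  ld <- log(d); ls <- log(s)
  model <- function(p) {
    # p = (logC, s1, s2, logPhi)
    p[1] + p[2] * ld + ((p[3] - p[2]) / gamma) *
      log1p(exp(gamma * (ld - p[4])))
  }
  sse <- function(p) {
    r <- ls - model(p)
    sum(r * r)
  }
  # slope guesses from the first and last decades
  lo <- d <= min(d) * 10
  hi <- d >= max(d) / 10
  slope <- function(m) {
    if (sum(m) >= 2) unname(coef(lm(ls[m] ~ ld[m]))[2]) else 1.5
  }
  s1_0 <- slope(lo); s2_0 <- slope(hi)
  phi_cand <- unique(pmin(pmax(
    stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE),
    min(d)), max(d)))
  fits <- list()
  for (phi0 in phi_cand) {
    start <- c(logC = ls[1] - s1_0 * ld[1], s1 = s1_0, s2 = s2_0,
               logPhi = log(phi0))
    f <- tryCatch(
      stats::optim(start, sse, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(f)) {
      # polish with L-M on the residual vector
      f2 <- tryCatch({
        nf <- minpack.lm::nls.lm(par = f$par,
                                 fn = function(p) ls - model(p),
                                 control = minpack.lm::nls.lm.control(
                                   maxiter = 200))
        list(par = nf$par, value = sum(residuals(nf)^2), conv = TRUE)
      }, error = function(e) list(par = f$par, value = f$value,
                                  conv = f$convergence == 0))
      fits[[length(fits) + 1]] <- f2
    }
  }
  if (!length(fits)) return(empty_fit())
  vals <- vapply(fits, `[[`, numeric(1), "value")
  phis <- vapply(fits, function(f) exp(f$par[[4]]), numeric(1))
  best <- order(vals, phis)[1]
  p <- fits[[best]]$par
  Phi <- exp(p[[4]])
  phi_ok <- abs(p[[2]] - p[[3]]) > 0.05 && Phi > min(d) && Phi < max(d)
  structure(list(C = exp(p[[1]]), sigma1 = p[[2]], sigma2 = p[[3]],
                 Phi = Phi, gamma = gamma, chi = p[[2]], chi_lg = p[[3]],
                 residual = vals[best] / n, converged = isTRUE(fits[[best]]$conv),
                 low_confidence = low_conf, phi_identifiable = phi_ok,
                 n_points = n),
            class = "double_powerlaw_fit")
}

#' @export
print.double_powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "Double power-law fit: sigma1 (chi) = %.3f, sigma2 (chi_lg) = %.3f, Phi = %.1f\n",
    x$sigma1, x$sigma2, x$Phi))
  cat(sprintf("  C = %.3g, gamma = %g, mean sq log-residual = %.3g\n",
              x$C, x$gamma, x$residual))
  if (!x$phi_identifiable) cat("  note: transition point not identifiable\n")
  if (x$low_confidence) cat("  note: low confidence (few or narrow durations)\n")
  invisible(x)
}

#' Evaluate a double power-law curve
#'
#' Forward evaluation of the fitted functional form; useful for computing
#' the size cutoff at the transition point and for generating synthetic
#' curves.
#'
#' @param d durations at which to evaluate.
#' @param C,sigma1,sigma2,Phi,gamma curve parameters.
#' @return Numeric vector `S(d)`.
#' @export
double_powerlaw <- function(d, C, sigma1, sigma2, Phi, gamma = 4) {
  C * d^sigma1 * (1 + (d / Phi)^gamma)^((sigma2 - sigma1) / gamma)
}

#' Truncated power-law exponent by maximum likelihood
#'
#' Maximum-likelihood estimate of the exponent `a` of a power law
#' \eqn{P(x) \propto x^{-a}} truncated to `[xmin, xmax]`.  For integer data
#' the discrete law is used (normalization by the generalized harmonic sum
#' over the support); for real-valued data the continuous law.  The
#' estimate is scale-invariant in the sample (duplicating the sample leaves
#' it unchanged) and its standard error is obtained from the curvature of
#' the log-likelihood at the maximum.
#'
#' @param x numeric sample (sizes or durations).
#' @param xmin,xmax truncation bounds (`xmin < xmax`).
#' @param discrete logical; default `NULL` auto-detects integer-valued data.
#' @param min_samples minimum in-range sample size before the estimate is
#'   flagged low-confidence (default 50).
#' @return List with `exponent`, `se`, `n`, `discrete`, `low_confidence`,
#'   `xmin`, `xmax`.
#' @export
fit_truncated_powerlaw <- function(x, xmin, xmax, discrete = NULL,
                                   min_samples = 50) {
  if (!is.finite(xmin) || !is.finite(xmax) || xmin >= xmax)
    stop("need finite xmin < xmax")
  x <- x[is.finite(x) & x >= xmin & x <= xmax]
  n <- length(x)
  if (is.null(discrete)) discrete <- all(x == round(x))
  out <- list(exponent = NA_real_, se = NA_real_, n = n,
              discrete = discrete, low_confidence = n < min_samples,
              xmin = xmin, xmax = xmax)
  if (n < 2) return(out)
  slx <- sum(log(x))
  if (discrete && (xmax - xmin) <= 5e6) {
    support <- seq(ceiling(xmin), floor(xmax))
    lsup <- log(support)
    logZ <- function(a) {
      m <- max(-a * lsup)
      m + log(sum(exp(-a * lsup - m)))
    }
  } else {
    logZ <- function(a) {
      if (abs(a - 1) < 1e-9) return(log(log(xmax / xmin)))
      log(abs((xmax^(1 - a) - xmin^(1 - a)) / (1 - a)))
    }
  }
  nll <- function(a) a * slx + n * logZ(a)
  opt <- stats::optimize(nll, interval = c(0.05, 6), tol = 1e-6)
  a_hat <- opt$minimum
  h <- 1e-4
  d2 <- (nll(a_hat + h) - 2 * nll(a_hat) + nll(a_hat - h)) / h^2
  out$exponent <- a_hat
  out$se <- if (is.finite(d2) && d2 > 0) 1 / sqrt(d2) else NA_real_
  out
}

#' Truncated power-law exponent by binned log-log regression
#'
#' Alternative estimator: logarithmically binned histogram of the in-range
#' sample, least-squares slope of log density versus log bin center.
#' Provided as a cross-check for [fit_truncated_powerlaw()]; the MLE is the
#' default throughout the package.
#'
#' @inheritParams fit_truncated_powerlaw
#' @param bins_per_decade number of logarithmic bins per decade (default 8).
#' @return List with `exponent`, `n`, `n_bins`.
#' @export
fit_powerlaw_binned <- function(x, xmin, xmax, bins_per_decade = 8) {
  x <- x[is.finite(x) & x >= xmin & x <= xmax]
  if (length(x) < 2 || xmin >= xmax)
    return(list(exponent = NA_real_, n = length(x), n_bins = 0L))
  nb <- max(3, ceiling(log10(xmax / xmin) * bins_per_decade))
  edges <- exp(seq(log(xmin), log(xmax * (1 + 1e-9)), length.out = nb + 1))
  h <- graphics::hist(x, breaks = edges, plot = FALSE)
  dens <- h$counts / diff(edges)
  ok <- dens > 0
  if (sum(ok) < 3)
    return(list(exponent = NA_real_, n = length(x), n_bins = sum(ok)))
  fitc <- coef(lm(log(dens[ok]) ~ log(h$mids[ok])))
  list(exponent = -unname(fitc[2]), n = length(x), n_bins = sum(ok))
}

#' Crackling-noise prediction of the scaling exponent
#'
#' \eqn{\chi_{cn} = (\beta - 1)/(\alpha - 1)} from the size exponent
#' \eqn{\alpha} and duration exponent \eqn{\beta}.  When \eqn{\alpha} lies
#' within `eps` of 1 the prediction passes through a singularity and is
#' returned as `NA` with the `singular` flag set.
#'
#' @param alpha size-distribution exponent.
#' @param beta duration-distribution exponent.
#' @param eps singularity guard half-width around `alpha = 1` (default 0.02).
#' @return List with `chi_cn` and `singular`.
#' @examples
#' crackling_prediction(1.5, 2)$chi_cn  # 2
#' @export
crackling_prediction <- function(alpha, beta, eps = 0.02) {
  if (!is.finite(alpha) || !is.finite(beta))
    return(list(chi_cn = NA_real_, singular = FALSE))
  if (abs(alpha - 1) <= eps)
    return(list(chi_cn = NA_real_, singular = TRUE))
  list(chi_cn = (beta - 1) / (alpha - 1), singular = FALSE)
}

#' Full exponent suite for one avalanche set
#'
#' The complete per-parameter-cell analysis: fit the double power law to
#' the mean size-duration curve (yielding \eqn{\chi}, \eqn{\chi_{lg}} and
#' the transition point \eqn{\Phi}), then the size exponent \eqn{\alpha}
#' by truncated MLE on `[size_min, S(Phi)]` (lower cutoff above the Poisson
#' noise floor, upper cutoff the fitted mean size at \eqn{\Phi}), the
#' duration exponent \eqn{\beta} on `[dur_min, Phi]`, the crackling-noise
#' prediction \eqn{\chi_{cn}} and the deviation-from-criticality
#' coefficient \eqn{DCC = \chi - \chi_{cn}}.
#'
#' Exponents are only considered valid when at least one avalanche exceeds
#' 20 generations (bins); otherwise every estimate is `NA` with
#' `valid = FALSE`.  `mode = "first4"` estimates \eqn{\chi} from the first
#' four generations only (log-log regression on durations 1-4), the
#' convention used for short frame-based recordings.
#'
#' @param av an avalanche set (from [avalanche_pipeline()]).
#' @param mode `"full"` (default) or `"first4"`.
#' @param size_min lower size cutoff (default 100).
#' @param dur_min lower duration cutoff in bins (default 3).
#' @param min_long_duration validity rule: require at least one avalanche
#'   longer than this many bins (default 20).
#' @param eps singularity guard for [crackling_prediction()].
#' @param gamma transition sharpness for the double power-law fit.
#' @return Object of class `"exponent_set"`: list with `alpha`, `alpha_se`,
#'   `beta`, `beta_se`, `chi`, `chi_lg`, `Phi`, `chi_cn`, `dcc`, `valid`,
#'   `singular`, `n_avalanches`, `flags` (character), and the cutoffs used.
#' @export
exponent_suite <- function(av, mode = c("full", "first4"), size_min = 100,
                           dur_min = 3, min_long_duration = 20, eps = 0.02,
                           gamma = 4) {
  mode <- match.arg(mode)
  empty <- structure(list(
    alpha = NA_real_, alpha_se = NA_real_, beta = NA_real_,
    beta_se = NA_real_, chi = NA_real_, chi_lg = NA_real_, Phi = NA_real_,
    chi_cn = NA_real_, dcc = NA_real_, valid = FALSE, singular = FALSE,
    n_avalanches = nrow(av), mode = mode, size_min = size_min,
    dur_min = dur_min, size_max = NA_real_, flags = character(0)),
    class = "exponent_set")
  if (!nrow(av)) {
    empty$flags <- "empty-set"
    return(empty)
  }
  if (max(av$duration) <= min_long_duration) {
    empty$flags <- "no-avalanche-beyond-20-generations"
    return(empty)
  }
  out <- empty
  out$valid <- TRUE
  curve <- mean_size_by_duration(av)
  fit <- fit_double_powerlaw(curve, gamma = gamma)
  out$Phi <- fit$Phi
  out$chi_lg <- fit$chi_lg
  if (!fit$converged) out$flags <- c(out$flags, "scaling-fit-not-converged")
  if (fit$low_confidence) out$flags <- c(out$flags, "scaling-fit-low-confidence")
  if (mode == "full") {
    out$chi <- fit$chi
  } else {
    m <- curve$duration <= 4
    if (sum(m) >= 2) {
      out$chi <- unname(coef(lm(log(curve$mean_size[m]) ~
                                  log(curve$duration[m])))[2])
    } else {
      out$flags <- c(out$flags, "too-few-short-durations")
    }
  }
  size_max <- if (is.finite(fit$Phi)) {
    double_powerlaw(fit$Phi, fit$C, fit$sigma1, fit$sigma2, fit$Phi, gamma)
  } else NA_real_
  out$size_max <- size_max
  if (is.finite(size_max) && size_max > size_min) {
    af <- fit_truncated_powerlaw(av$size, size_min, size_max)
    out$alpha <- af$exponent; out$alpha_se <- af$se
    if (af$low_confidence) out$flags <- c(out$flags, "alpha-low-confidence")
  } else {
    out$flags <- c(out$flags, "alpha-cutoffs-degenerate")
  }
  if (is.finite(fit$Phi) && fit$Phi > dur_min) {
    bf <- fit_truncated_powerlaw(av$duration, dur_min, fit$Phi)
    out$beta <- bf$exponent; out$beta_se <- bf$se
    if (bf$low_confidence) out$flags <- c(out$flags, "beta-low-confidence")
  } else {
    out$flags <- c(out$flags, "beta-cutoffs-degenerate")
  }
  cn <- crackling_prediction(out$alpha, out$beta, eps = eps)
  out$chi_cn <- cn$chi_cn
  out$singular <- cn$singular
  if (is.finite(out$chi) && is.finite(out$chi_cn))
    out$dcc <- out$chi - out$chi_cn
  out
}

#' @export
print.exponent_set <- function(x, ...) {
  if (!x$valid) {
    cat("Exponent set: invalid (", paste(x$flags, collapse = ", "), ")\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Exponent set (%s): chi = %.3f, chi_lg = %.3f, alpha = %.3f, beta = %.3f\n",
    x$mode, x$chi, x$chi_lg, x$alpha, x$beta))
  cat(sprintf("  Phi = %.1f, chi_cn = %s, DCC = %s, n = %d\n",
              x$Phi,
              if (x$singular) "singular" else sprintf("%.3f", x$chi_cn),
              if (is.finite(x$dcc)) sprintf("%.3f", x$dcc) else "NA",
              x$n_avalanches))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Scaling exponent as a function of coarse-graining
#'
#' Convenience wrapper computing \eqn{\chi(k)} over a grid of
#' coarse-graining factors at fixed sampling fraction and threshold.
#'
#' @param x input accepted by [avalanche_pipeline()].
#' @param f sampling fraction.
#' @param theta threshold.
#' @param k_grid integer vector of coarse-graining factors.
#' @param mode passed to [exponent_suite()].
#' @param ... further arguments to [exponent_suite()].
#' @return Data frame `k`, `chi`, `valid`, `n_avalanches`.
#' @export
chi_vs_k <- function(x, f = 1, theta = 1, k_grid = 2^(0:7), mode = "full",
                     ...) {
  rows <- lapply(k_grid, function(k) {
    av <- avalanche_pipeline(x, f = f, k = k, theta = theta)
    es <- exponent_suite(av, mode = mode, ...)
    data.frame(k = k, chi = es$chi, valid = es$valid && is.finite(es$chi),
               n_avalanches = es$n_avalanches)
  })
  do.call(rbind, rows)
}

#' Exponent rescue map over coarse-graining and threshold
#'
#' Computes the full exponent suite on every cell of a `(k, theta)` grid,
#' the consolidated view in which the rescue of \eqn{\chi = 2} by combined
#' coarse-graining and thresholding appears as a contiguous band.  On
#' integer spike data, cells whose threshold falls below the one-spike
#' resolution (`theta < 1`) are masked as unobservable.  With
#' `consolidate = TRUE` the supplied thresholds are interpreted on the
#' fully sampled scale and rescaled to `f * theta` before extraction, which
#' aligns maps across sampling fractions.
#'
#' @param x input accepted by [avalanche_pipeline()].
#' @param f sampling fraction.
#' @param k_grid,theta_grid strictly increasing grids.
#' @param mode passed to [exponent_suite()].
#' @param consolidate rescale thresholds by `f` (default `FALSE`).
#' @param ... further arguments to [exponent_suite()].
#' @return Long-format data frame `k`, `theta`, `alpha`, `beta`, `chi`,
#'   `chi_lg`, `chi_cn`, `dcc`, `valid`, `unobservable`, `singular`.
#' @export
rescue_map <- function(x, f = 1, k_grid = 2^(0:6),
                       theta_grid = 10^(0:3), mode = "full",
                       consolidate = FALSE, ...) {
  if (!length(k_grid) || !length(theta_grid) ||
      is.unsorted(k_grid, strictly = TRUE) ||
      is.unsorted(theta_grid, strictly = TRUE))
    stop("grids must be non-empty and strictly increasing")
  rows <- list()
  for (theta in theta_grid) {
    th_eff <- if (consolidate) theta * f else theta
    for (k in k_grid) {
      av <- avalanche_pipeline(x, f = f, k = k, theta = th_eff)
      unobs <- isTRUE(attr(av, "unobservable"))
      es <- if (unobs) NULL else exponent_suite(av, mode = mode, ...)
      rows[[length(rows) + 1]] <- data.frame(
        k = k, theta = theta,
        alpha = if (unobs) NA_real_ else es$alpha,
        beta = if (unobs) NA_real_ else es$beta,
        chi = if (unobs) NA_real_ else es$chi,
        chi_lg = if (unobs) NA_real_ else es$chi_lg,
        chi_cn = if (unobs) NA_real_ else es$chi_cn,
        dcc = if (unobs) NA_real_ else es$dcc,
        valid = if (unobs) FALSE else es$valid,
        unobservable = unobs,
        singular = if (unobs) FALSE else es$singular)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "f") <- f
  attr(out, "consolidate") <- consolidate
  out
}
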
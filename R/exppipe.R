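#' Synthetic two-photon-style recordings from the critical model
#'
#' Generates a set of synthetic recordings emulating cellular-resolution
#' calcium-imaging sessions: each recording tracks a few hundred ROIs
#' (a fractionally sampled subset of the simulated network), maps
#' simulation time steps to imaging frames by temporal summation, converts
#' integer spikes to non-negative spike densities through a per-ROI gain,
#' and adds a truncated-normal noise floor.  A lognormal rate multiplier
#' across recordings emulates session-to-session variability, which gives
#' the avalanche-number-versus-threshold curves their lognormal spread.
#'
#' @param params network parameters ([make_params()]); the default uses a
#'   3e5-neuron critical network so that 200-400 ROIs correspond to a
#'   sampling fraction near 1e-3.  The generator is meaningful for the
#'   critical balance `g = 3.5` and its failure mode for subcritical `g`.
#' @param n_rec number of recordings (default 17).
#' @param n_roi_range inclusive range of ROI counts per recording
#'   (default `c(200, 400)`); the sampling fraction is `n_roi / N`.
#' @param duration_s recording duration in seconds (default 1800, i.e.
#'   30 minutes).
#' @param frame_rate imaging frame rate in Hz (default 45.527).
#' @param steps_per_frame simulation time steps summed into one frame
#'   (default 22, i.e. a ~1 ms model step at the 45.527 Hz frame rate).
#' @param gain_meanlog,gain_sdlog lognormal per-ROI gain converting spikes
#'   to spike density (defaults 0 and 0.2).
#' @param noise_sd standard deviation of the additive truncated-normal
#'   (at zero) noise floor per ROI and frame (default 0.02).
#' @param baseline_mean,baseline_sdlog,baseline_tau_s shared slowly
#'   drifting baseline: a lognormal amplitude with median
#'   `baseline_mean * n_roi`, log-scale spread `baseline_sdlog` and an
#'   AR(1) autocorrelation time of `baseline_tau_s` seconds, distributed
#'   over ROIs in proportion to their gains (defaults 0.02, 0.7 and 2;
#'   `baseline_mean = 0` disables it).  This emulates frame-wide
#'   correlated noise (neuropil and motion residues) and gives the
#'   avalanche-number-versus-threshold curve its lognormal left branch.
#' @param rate_sdlog lognormal spread of the per-recording amplitude
#'   multiplier (default 0.3).
#' @param seed integer seed; two calls with the same seed are identical.
#' @return List of `"recording_raster"` objects: each a list with
#'   `density` (ROI x frame matrix), `frame_rate`, `duration_s`,
#'   `recording_id`, `f`, `rate_mult`, `seed_used`.
#' @export
generate_recordings <- function(params = make_params(N = 3e5), n_rec = 17,
                                n_roi_range = c(200, 400),
                                duration_s = 1800, frame_rate = 45.527,
                                steps_per_frame = 22,
                                gain_meanlog = 0, gain_sdlog = 0.2,
                                noise_sd = 0.02, rate_sdlog = 0.3,
                                baseline_mean = 0.02, baseline_sdlog = 0.7,
                                baseline_tau_s = 2, seed = NULL) {
  if (n_rec < 1) stop("n_rec must be >= 1")
  if (duration_s <= 0 || frame_rate <= 0 || steps_per_frame < 1)
    stop("invalid recording dimensions")
  if (!is.null(seed)) set.seed(seed)
  frames <- floor(duration_s * frame_rate)
  if (frames < 2) stop("recording too short for the requested frame rate")
  lapply(seq_len(n_rec), function(r) {
    n_roi <- sample(seq(n_roi_range[1], n_roi_range[2]), 1)
    f <- n_roi / params$N
    rast <- simulate_raster(params, M = n_roi,
                            steps = frames * steps_per_frame)
    m <- raster_matrix(rast)
    counts <- matrix(0, nrow = n_roi, ncol = frames)
    for (b in seq_len(steps_per_frame)) {
      counts <- counts +
        m[, seq(b, by = steps_per_frame, length.out = frames), drop = FALSE]
    }
    gain <- stats::rlnorm(n_roi, gain_meanlog, gain_sdlog)
    rate_mult <- stats::rlnorm(1, 0, rate_sdlog)
    noise <- if (noise_sd > 0) {
      pmax(matrix(stats::rnorm(n_roi * frames, 0, noise_sd),
                  nrow = n_roi), 0)
    } else 0
    baseline <- if (baseline_mean > 0) {
      # AR(1) in log space: slow shared drift with the stationary
      # lognormal marginal (median baseline_mean * n_roi, sd baseline_sdlog)
      phi <- exp(-1 / (baseline_tau_s * frame_rate))
      eps <- stats::rnorm(frames, 0, baseline_sdlog * sqrt(1 - phi^2))
      lb <- stats::filter(eps, phi, method = "recursive",
                          init = stats::rnorm(1, 0, baseline_sdlog))
      glob <- exp(log(baseline_mean * n_roi) + as.numeric(lb))
      (gain / sum(gain)) %o% glob
    } else 0
    density <- rate_mult * (gain * counts) + noise + baseline
    structure(list(density = density, frame_rate = frame_rate,
                   duration_s = duration_s, recording_id = r, f = f,
                   rate_mult = rate_mult, n_roi = n_roi,
                   g = params$g),
              class = "recording_raster")
  })
}

#' @export
print.recording_raster <- function(x, ...) {
  cat(sprintf(
    "Recording %d: %d ROIs x %d frames at %.3f Hz (f = %.2g, g = %g)\n",
    x$recording_id, nrow(x$density), ncol(x$density), x$frame_rate,
    x$f, x$g))
  invisible(x)
}

#' Population spike-density trace of a recording
#'
#' @param rec a `"recording_raster"`.
#' @return Numeric vector: per-frame sum of spike density over ROIs.
#' @export
recording_activity <- function(rec) {
  stopifnot(inherits(rec, "recording_raster"))
  colSums(rec$density)
}

#' Avalanche number as a function of threshold
#'
#' Counts avalanches in the coarse-grained population activity of a
#' recording at every threshold of a grid, then fits a Gaussian in
#' `log(theta)` to the count curve by least squares.  The fitted location
#' and scale define the recording- and `k`-specific z-map
#' `z(theta) = (log(theta) - mu) / sigma`, used to place thresholds on a
#' comparable scale across recordings.
#'
#' @param x a `"recording_raster"` or a numeric population activity vector.
#' @param theta_grid positive, increasing threshold grid (spike-density
#'   units; real-valued thresholds are allowed).
#' @param k coarse-graining factor in frames (default 1).
#' @return Object of class `"threshold_number_curve"`: list with `curve`
#'   (data frame `theta`, `n_avalanches`), `mu`, `sigma`, `amplitude`,
#'   `r_squared`, `fit_ok`, `k`, plus helper fields used by
#'   [threshold_for_z()].
#' @export
avalanche_count_vs_threshold <- function(x, theta_grid, k = 1) {
  act <- if (inherits(x, "recording_raster")) recording_activity(x)
         else as.numeric(x)
  if (any(theta_grid <= 0)) stop("theta grid must be positive")
  if (all(act == 0)) {
    return(structure(list(curve = NULL, mu = NA_real_, sigma = NA_real_,
                          amplitude = NA_real_, r_squared = NA_real_,
                          fit_ok = FALSE, k = k, empty = TRUE),
                     class = "threshold_number_curve"))
  }
  cg <- coarse_grain(act, k)
  counts <- vapply(theta_grid, function(th) {
    nrow(extract_avalanches(apply_threshold(cg, th)))
  }, numeric(1))
  curve <- data.frame(theta = theta_grid, n_avalanches = counts)
  lth <- log(theta_grid)
  fit_ok <- FALSE
  mu <- sigma <- amp <- r2 <- NA_real_
  ok <- counts > 0
  if (sum(ok) >= 5) {
    # lognormal shape = parabola in (log theta, log count); fitting the
    # log-counts weights both tails of the curve, not just its peak
    ft <- lm(log(counts[ok]) ~ lth[ok] + I(lth[ok]^2))
    cf <- unname(coef(ft))
    if (is.finite(cf[3]) && cf[3] < 0) {
      mu <- -cf[2] / (2 * cf[3])
      sigma <- sqrt(-1 / (2 * cf[3]))
      amp <- exp(cf[1] - cf[2]^2 / (4 * cf[3]))
      r2 <- summary(ft)$r.squared
      fit_ok <- TRUE
    }
  }
  structure(list(curve = curve, mu = mu, sigma = sigma, amplitude = amp,
                 r_squared = r2, fit_ok = fit_ok, k = k, empty = FALSE),
            class = "threshold_number_curve")
}

#' Threshold corresponding to a z-scored position
#'
#' Inverts a fitted lognormal z-map: `theta = exp(mu + z * sigma)`.
#'
#' @param tnc a `"threshold_number_curve"` with `fit_ok = TRUE`.
#' @param z z-score (0 corresponds to the mode of the fitted curve).
#' @return Threshold in the recording's spike-density units (`NA` if the
#'   fit failed).
#' @export
threshold_for_z <- function(tnc, z) {
  stopifnot(inherits(tnc, "threshold_number_curve"))
  if (!isTRUE(tnc$fit_ok)) return(NA_real_)
  exp(tnc$mu + z * tnc$sigma)
}

#' z-scored (or pooled absolute-threshold) chi and DCC maps
#'
#' The recording-level rescue analysis.  In `"zscore"` mode, for each
#' recording and coarse-graining factor the avalanche-number curve is
#' fitted in `log(theta)` and each requested z value is converted to the
#' recording-specific threshold `exp(mu + z * sigma)`; avalanches are then
#' extracted and the exponent suite evaluated in `"first4"` mode (with the
#' at-least-one-avalanche-beyond-20-generations validity rule), and valid
#' `chi` and `DCC` values are averaged across recordings per `(z, k)`
#' cell.  In `"absolute"` mode all recordings' avalanches are pooled at
#' each fixed threshold of `threshold_grid`.
#'
#' @param recordings list of `"recording_raster"` objects.
#' @param z_grid z-scored threshold grid (mode `"zscore"`).
#' @param k_grid coarse-graining factors in frames.
#' @param mode `"zscore"` (default) or `"absolute"`.
#' @param threshold_grid absolute spike-density thresholds (mode
#'   `"absolute"`).
#' @param theta_fit_grid threshold grid used to fit the z-maps; default
#'   spans the observed activity range logarithmically.
#' @param chi_mode [exponent_suite()] mode for the per-cell fits
#'   (default `"first4"`, the short-recording convention).
#' @param size_min,dur_min cutoffs passed to [exponent_suite()]
#'   (defaults adapted to spike-density data: `size_min = 10`,
#'   `dur_min = 2`).
#' @param ... further arguments to [exponent_suite()].
#' @return Long-format data frame `k`, `z` (or `theta`), `chi`, `dcc`,
#'   `n_valid` (recordings contributing, or 1 for pooled mode), `masked`.
#' @export
zscored_chi_map <- function(recordings, z_grid = seq(-2, 1.5, by = 0.5),
                            k_grid = c(1, 2, 4, 8, 16, 32),
                            mode = c("zscore", "absolute"),
                            threshold_grid = NULL, theta_fit_grid = NULL,
                            chi_mode = "first4",
                            size_min = 10, dur_min = 2, ...) {
  mode <- match.arg(mode)
  stopifnot(length(recordings) >= 1)
  acts <- lapply(recordings, recording_activity)
  if (mode == "absolute") {
    if (is.null(threshold_grid))
      stop("absolute mode requires threshold_grid")
    rows <- list()
    for (k in k_grid) {
      for (th in threshold_grid) {
        av <- avalanche_pipeline(acts, k = k, theta = th)
        es <- exponent_suite(av, mode = chi_mode, size_min = size_min,
                             dur_min = dur_min, ...)
        rows[[length(rows) + 1]] <- data.frame(
          k = k, theta = th, chi = es$chi, dcc = es$dcc,
          n_valid = as.integer(es$valid && is.finite(es$chi)),
          masked = !es$valid)
      }
    }
    return(do.call(rbind, rows))
  }
  rows <- list()
  for (k in k_grid) {
    # per-recording z-maps at this k
    tncs <- lapply(acts, function(a) {
      grid <- theta_fit_grid
      if (is.null(grid)) {
        cg <- coarse_grain(a, k)
        top <- max(cg)
        if (top <= 0) return(NULL)
        grid <- exp(seq(log(max(min(cg[cg > 0]), 1e-3)), log(top),
                        length.out = 25))
      }
      avalanche_count_vs_threshold(a, grid, k = k)
    })
    for (z in z_grid) {
      chis <- c(); dccs <- c()
      for (i in seq_along(acts)) {
        tnc <- tncs[[i]]
        if (is.null(tnc) || !isTRUE(tnc$fit_ok)) next
        th <- threshold_for_z(tnc, z)
        if (!is.finite(th)) next
        av <- avalanche_pipeline(acts[[i]], k = k, theta = th)
        es <- exponent_suite(av, mode = chi_mode, size_min = size_min,
                             dur_min = dur_min, ...)
        if (es$valid && is.finite(es$chi)) {
          chis <- c(chis, es$chi)
          if (is.finite(es$dcc)) dccs <- c(dccs, es$dcc)
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        k = k, z = z,
        chi = if (length(chis)) mean(chis) else NA_real_,
        dcc = if (length(dccs)) mean(dccs) else NA_real_,
        n_valid = length(chis), masked = length(chis) == 0)
    }
  }
  do.call(rbind, rows)
}
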
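#' One exact population-count update step
#'
#' Advances the population spike counts of the balanced E/I network by one
#' time step.  Because weights are uniform within each class and the leak is
#' zero, every non-refractory neuron shares the membrane potential
#' `V = J*nE - g*J*nI`, and fires with probability
#' `p = 1 - (1 - clip(Gamma*V, 0, 1)) * (1 - lambda_drive)`
#' (membrane rule OR external drive, independently).  Neurons that fired at
#' the previous step are absolutely refractory.  The next-step counts are
#' therefore binomial draws over the non-refractory pools of each class.
#'
#' @param nE,nI excitatory/inhibitory spike counts at the current step.
#' @param params an [make_params()] object.
#' @return Named numeric vector `c(nE, nI, n_drive)` at the next step,
#'   where `n_drive` counts the spikes triggered by the external drive.
#' @examples
#' p <- make_params(g = 3.5)
#' step_counts(0, 0, p)   # ~Poisson(20) drive-triggered spikes
#' @export
step_counts <- function(nE, nI, params) {
  stopifnot(inherits(params, "avalanche_params"))
  if (nE < 0 || nI < 0 || nE > params$N_E || nI > params$N_I)
    stop("state counts outside class bounds")
  V <- params$J * nE - params$g * params$J * nI
  pm <- min(max(params$Gamma * V, 0), 1)
  poolE <- params$N_E - nE
  poolI <- params$N_I - nI
  dE <- stats::rbinom(1, poolE, params$lambda_drive)
  dI <- stats::rbinom(1, poolI, params$lambda_drive)
  mE <- stats::rbinom(1, poolE - dE, pm)
  mI <- stats::rbinom(1, poolI - dI, pm)
  c(nE = dE + mE, nI = dI + mI, n_drive = dE + dI)
}

#' Simulate the balanced E/I network with coupled subsampling
#'
#' Runs the exact population-count simulation for `n_runs` independent runs
#' of `steps` time steps each, starting every run from the all-quiescent
#' absorbing state.  For each requested sampling fraction `f` a coupled
#' subsampled observer is maintained: at every step the number of sampled
#' neurons that fired follows a hypergeometric draw of the fired neurons
#' within the sampled non-refractory pool, stratified by E/I class, so the
#' `f = 1` observer reproduces the population totals exactly.
#'
#' @param params an [make_params()] object (requires `mu = 0`).
#' @param steps time steps per run (`>= 1`).
#' @param n_runs number of independent runs (default 1).
#' @param sample_fractions numeric vector of sampling fractions in `(0, 1]`.
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `"ei_simulation"`: list with `params`,
#'   `steps`, `sample_fractions`, `seed` and `runs`, where each run holds
#'   integer vectors `nE`, `nI`, `n_drive` and a named list `sampled` of
#'   per-fraction sampled spike counts.
#' @examples
#' p <- make_params(g = 3.75, N = 1e4)
#' sim <- simulate_network(p, steps = 1000, sample_fractions = 1, seed = 1)
#' all.equal(sim$runs[[1]]$sampled[["1"]],
#'           sim$runs[[1]]$nE + sim$runs[[1]]$nI)
#' @export
simulate_network <- function(params, steps, n_runs = 1,
                             sample_fractions = numeric(0), seed = NULL) {
  stopifnot(inherits(params, "avalanche_params"))
  if (params$mu != 0)
    stop("the population-count simulator requires mu = 0 (non-leaky)")
  if (steps < 1) stop("steps must be >= 1")
  if (length(sample_fractions)) {
    if (any(sample_fractions <= 0 | sample_fractions > 1))
      stop("sample fractions must lie in (0, 1]")
    if (any(round(params$N * sample_fractions) < 1))
      stop("sample fraction implies fewer than one sampled neuron")
  }
  if (!is.null(seed)) set.seed(seed)
  M  <- round(params$N * sample_fractions)
  ME <- round(M * params$f_E)
  MI <- M - ME
  # full sampling must be exact: force class sizes to the population's
  full <- sample_fractions == 1
  ME[full] <- params$N_E
  MI[full] <- params$N_I
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    res <- sim_counts_cpp(as.integer(steps), params$N_E, params$N_I,
                          params$J, params$g, params$Gamma,
                          params$lambda_drive,
                          as.numeric(ME), as.numeric(MI),
                          params$drive_refractory_immune,
                          0, 0, numeric(length(ME)), numeric(length(MI)))
    sampled <- res$sampled
    names(sampled) <- as.character(sample_fractions)
    runs[[r]] <- list(nE = res$nE, nI = res$nI, n_drive = res$n_drive,
                      sampled = sampled, run_id = r)
  }
  structure(list(params = params, steps = steps,
                 sample_fractions = sample_fractions,
                 seed = seed, runs = runs),
            class = "ei_simulation")
}

#' @export
print.ei_simulation <- function(x, ...) {
  cat(sprintf("E/I network simulation: %d run(s) x %g steps (g = %g)\n",
              length(x$runs), x$steps, x$params$g))
  if (length(x$sample_fractions))
    cat("  coupled sampling fractions:",
        paste(x$sample_fractions, collapse = ", "), "\n")
  a <- activity(x$runs[[1]])
  cat(sprintf("  run 1 mean activity: %.2f spikes/step (max %d)\n",
              mean(a), max(a)))
  invisible(x)
}

#' Total population activity of a run
#'
#' @param run one element of `sim$runs` from [simulate_network()], or a list
#'   with `nE` and `nI` integer vectors.
#' @return Integer vector `a(t) = nE(t) + nI(t)`.
#' @export
activity <- function(run) run$nE + run$nI

#' Per-neuron spike raster of a tracked subset
#'
#' Simulates the network while explicitly tracking `M` neurons (stratified
#' E/I composition, `round(M * f_E)` excitatory).  Global population counts
#' evolve exactly as in [simulate_network()]; the tracked subset's fired
#' count per step is a coupled hypergeometric draw, and individual spikes
#' are allocated uniformly among the tracked non-refractory neurons of each
#' class (valid because all of them share the same firing probability).
#'
#' @param params an [make_params()] object.
#' @param M number of tracked neurons (`2 <= M <= N`).
#' @param steps number of time steps.
#' @param seed optional integer seed.
#' @return An object of class `"spike_raster"`: list with `events`
#'   (data.frame `neuron`, `t`; neuron ids `1..M`, excitatory first),
#'   `M`, `M_E`, `steps`, `counts` (per-step tracked spike totals), and the
#'   coupled population trace `trace` (`nE`, `nI`, `n_drive`).
#' @export
simulate_raster <- function(params, M, steps, seed = NULL) {
  stopifnot(inherits(params, "avalanche_params"))
  if (M > params$N) stop("M must not exceed N")
  if (M < 2) stop("M must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  ME <- round(M * params$f_E)
  MI <- M - ME
  res <- sim_raster_cpp(as.integer(steps), params$N_E, params$N_I,
                        params$J, params$g, params$Gamma,
                        params$lambda_drive, as.integer(ME), as.integer(MI))
  structure(list(
    events = data.frame(neuron = res$neuron, t = res$t),
    M = M, M_E = ME, steps = steps, counts = res$sampled_count,
    trace = list(nE = res$nE, nI = res$nI, n_drive = res$n_drive),
    seed = seed
  ), class = "spike_raster")
}

#' Dense matrix view of a spike raster
#'
#' @param raster a [simulate_raster()] object.
#' @return Integer matrix `M x steps` of 0/1 spikes.
#' @export
raster_matrix <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  m <- matrix(0L, nrow = raster$M, ncol = raster$steps)
  if (nrow(raster$events))
    m[cbind(raster$events$neuron, raster$events$t)] <- 1L
  m
}

#' Empirical branching ratio of an activity trace
#'
#' Drive-corrected estimator of the per-spike branching ratio: the mean
#' over eligible steps of `(a(t+1) - N*lambda) / a(t)`, with eligibility
#' restricted to `floor < a(t) < ceiling`.  The window matters because the
#' firing probability is rectified at zero: at very low activity the E/I
#' composition fluctuations are rectified upward, inflating the conditional
#' branching above the mean-field value, while near saturation the
#' shrinking non-refractory pool deflates it.  In the moderate-activity
#' window both effects are negligible and the estimate tracks the
#' mean-field ratio \eqn{\sigma(g)}, crossing 1 at the critical balance.
#'
#' @param run a simulation run (list with `nE`, `nI`) or a numeric activity
#'   vector.
#' @param params the [make_params()] object used in the simulation.
#' @param floor,ceiling eligibility window on `a(t)`; defaults
#'   `50 * N * lambda` (well above the drive noise floor) and `N / 100`
#'   (well below refractory saturation).
#' @return List with `sigma` (estimate, `NA` if no eligible steps),
#'   `n_eligible`, and `defined` flag.
#' @export
branching_ratio <- function(run, params, floor = NULL, ceiling = NULL) {
  stopifnot(inherits(params, "avalanche_params"))
  a <- if (is.list(run)) activity(run) else as.numeric(run)
  if (length(a) < 2) stop("trace must have at least 2 steps")
  if (is.null(floor)) floor <- 50 * params$N * params$lambda_drive
  if (is.null(ceiling)) ceiling <- params$N / 100
  drive <- params$N * params$lambda_drive
  cur <- a[-length(a)]
  nxt <- a[-1]
  ok <- cur > floor & cur < ceiling
  if (!any(ok))
    return(list(sigma = NA_real_, n_eligible = 0L, defined = FALSE))
  list(sigma = mean((nxt[ok] - drive) / cur[ok]),
       n_eligible = sum(ok), defined = TRUE)
}

#' Locate the critical balance by a branching-ratio sweep
#'
#' Simulates the network over a grid of E/I balance values `g` (holding the
#' default synaptic weight rule fixed), estimates the empirical branching
#' ratio at each, and locates the balance at which it crosses 1 by linear
#' interpolation between the bracketing grid points.
#'
#' @param g_grid balance values to sweep (increasing).
#' @param steps,n_runs simulation length per balance value.
#' @param seed integer seed.
#' @param ... overrides forwarded to [make_params()] (e.g. `N`).
#' @return List with `sweep` (data frame `g`, `sigma_hat`, `sigma_mf`,
#'   `n_eligible`) and `g_c_hat` (interpolated crossing, `NA` if the sweep
#'   does not bracket 1).
#' @export
criticality_sweep <- function(g_grid = c(3.3, 3.4, 3.45, 3.5, 3.55, 3.6, 3.75),
                              steps = 2e5, n_runs = 10, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(g_grid, function(g) {
    p <- make_params(g = g, ...)
    sim <- simulate_network(p, steps = steps, n_runs = n_runs)
    ests <- lapply(sim$runs, branching_ratio, params = p)
    ns <- vapply(ests, `[[`, numeric(1), "n_eligible")
    sig <- vapply(ests, function(e) e$sigma %||% NA_real_, numeric(1))
    ok <- is.finite(sig) & ns > 0
    data.frame(g = g,
               sigma_hat = if (any(ok)) sum(sig[ok] * ns[ok]) / sum(ns[ok])
                           else NA_real_,
               sigma_mf = mean_field_sigma(p),
               n_eligible = sum(ns))
  })
  sweep <- do.call(rbind, rows)
  ok <- is.finite(sweep$sigma_hat)
  g_c_hat <- NA_real_
  gs <- sweep$g[ok]; ss <- sweep$sigma_hat[ok]
  cross <- which(diff(ss >= 1) == -1)
  if (length(cross)) {
    i <- cross[1]
    g_c_hat <- gs[i] + (1 - ss[i]) * (gs[i + 1] - gs[i]) / (ss[i + 1] - ss[i])
  }
  list(sweep = sweep, g_c_hat = g_c_hat)
}
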
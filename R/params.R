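#' Model parameters for the balanced E/I branching network
#'
#' Constructs the parameter set of the all-to-all network of stochastic
#' non-leaky integrate-and-fire neurons: `N` neurons, a fraction `f_E` of
#' them excitatory, uniform synaptic weights `J` (excitatory outgoing) and
#' `-g*J` (inhibitory outgoing), neuronal gain `Gamma`, leak `mu` (only the
#' non-leaky case `mu = 0` is supported by the simulator) and an external
#' Poisson drive of rate `lambda_drive` per neuron per time step.
#'
#' When `J` is not supplied it is fixed by requiring the mean-field
#' branching ratio \eqn{\sigma(g) = N \Gamma J (f_E - g (1 - f_E))} to equal
#' 1 exactly at the critical balance `g_c = 3.5`, i.e.
#' `J = 1 / (N * Gamma * (f_E - g_c * (1 - f_E)))`.  With the defaults
#' (`N = 1e6`, `Gamma = 1`, `f_E = 0.8`) this gives `J = 1e-5`, so the
#' network is critical at `g = 3.5`, subcritical (inhibition-dominated) for
#' `g > 3.5` and supercritical for `g < 3.5`.
#'
#' @param g E/I balance parameter scaling inhibitory weights (dimensionless,
#'   `g >= 0`).
#' @param N total number of neurons (default `1e6`).
#' @param f_E excitatory fraction (default 0.8, i.e. a 4:1 E/I ratio).
#' @param Gamma neuronal gain (default 1).
#' @param mu leak parameter (default 0; the simulator requires 0).
#' @param lambda_drive per-neuron external firing probability per time step
#'   (default `2e-5`, which triggers on average `N * lambda_drive = 20`
#'   neurons per step at the default network size).
#' @param J excitatory synaptic weight; `NULL` (default) applies the
#'   critical-balance rule above.
#' @param g_c balance value at which the default `J` rule sets the
#'   branching ratio to 1 (default 3.5).
#' @param drive_refractory_immune logical; if `TRUE` (default) the external
#'   drive cannot excite neurons in their absolute refractory period.
#' @return An object of class `"avalanche_params"`: a list with fields
#'   `N`, `N_E`, `N_I`, `f_E`, `g`, `J`, `Gamma`, `mu`, `lambda_drive`,
#'   `g_c`, `sigma` (the mean-field branching ratio at `g`).
#' @examples
#' p <- make_params(g = 3.5)
#' p$J          # 1e-5
#' p$sigma      # 1 (critical)
#' make_params(g = 3.75)$sigma   # 0.5 (subcritical)
#' @seealso [simulate_network()], [branching_ratio()]
#' @export
make_params <- function(g = 3.5, N = 1e6, f_E = 0.8, Gamma = 1, mu = 0,
                        lambda_drive = 2e-5, J = NULL, g_c = 3.5,
                        drive_refractory_immune = TRUE) {
  if (!is.numeric(N) || length(N) != 1 || N < 10)
    stop("N must be a single number >= 10")
  if (!is.numeric(g) || length(g) != 1 || g < 0)
    stop("g must be a single non-negative number")
  if (!is.numeric(f_E) || f_E <= 0 || f_E >= 1)
    stop("f_E must lie strictly between 0 and 1")
  if (!is.numeric(lambda_drive) || lambda_drive < 0 || lambda_drive > 1)
    stop("lambda_drive must lie in [0, 1]")
  if (!is.numeric(Gamma) || Gamma <= 0)
    stop("Gamma must be positive")
  N_E <- round(N * f_E)
  N_I <- N - N_E
  if (is.null(J)) {
    denom <- f_E - g_c * (1 - f_E)
    if (denom <= 0)
      stop("default J rule requires f_E - g_c*(1 - f_E) > 0")
    J <- 1 / (N * Gamma * denom)
  }
  if (!is.numeric(J) || J <= 0) stop("J must be positive")
  p <- structure(list(
    N = N, N_E = N_E, N_I = N_I, f_E = f_E, g = g, J = J,
    Gamma = Gamma, mu = mu, lambda_drive = lambda_drive, g_c = g_c,
    drive_refractory_immune = isTRUE(drive_refractory_immune)
  ), class = "avalanche_params")
  p$sigma <- mean_field_sigma(p)
  p
}

#' Mean-field branching ratio of a parameter set
#'
#' \eqn{\sigma(g) = N \Gamma J (f_E - g (1 - f_E))}: the expected number of
#' spikes triggered per spike in the low-activity limit.  \eqn{\sigma = 1}
#' defines criticality.
#'
#' @param params an [make_params()] object.
#' @param g optional balance value at which to evaluate (defaults to
#'   `params$g`); `J` is held fixed.
#' @return Numeric branching ratio.
#' @export
mean_field_sigma <- function(params, g = params$g) {
  stopifnot(inherits(params, "avalanche_params"))
  params$N * params$Gamma * params$J * (params$f_E - g * (1 - params$f_E))
}

#' @export
print.avalanche_params <- function(x, ...) {
  cat("Balanced E/I network parameters\n")
  cat(sprintf("  N = %g (E: %g, I: %g), g = %g (g_c = %g)\n",
              x$N, x$N_E, x$N_I, x$g, x$g_c))
  cat(sprintf("  J = %g, Gamma = %g, mu = %g, lambda = %g\n",
              x$J, x$Gamma, x$mu, x$lambda_drive))
  cat(sprintf("  mean-field branching ratio sigma = %g\n", x$sigma))
  invisible(x)
}
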
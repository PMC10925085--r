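# Independent oracles used across the suite.

# Explicit per-neuron one-step update of the balanced E/I network, written
# directly from the membrane/firing rules with no shared code with the
# package's count-based simulator.  `fired` is a logical vector (length N)
# marking neurons that fired at the current step; class is fixed by index
# (first N_E excitatory).
oracle_step_perneuron <- function(fired, params) {
  N_E <- params$N_E
  N <- params$N
  nE <- sum(fired[seq_len(N_E)])
  nI <- sum(fired[seq(N_E + 1, N)])
  V <- params$J * nE - params$g * params$J * nI
  pm <- min(max(params$Gamma * V, 0), 1)
  p <- 1 - (1 - pm) * (1 - params$lambda_drive)
  new_fired <- logical(N)
  nonrefr <- which(!fired)
  new_fired[nonrefr] <- runif(length(nonrefr)) < p
  new_fired
}

# Explicit per-neuron trajectory (slow; small N only).
oracle_simulate_perneuron <- function(params, steps) {
  fired <- logical(params$N)
  a <- integer(steps)
  for (t in seq_len(steps)) {
    fired <- oracle_step_perneuron(fired, params)
    a[t] <- sum(fired)
  }
  a
}

# Inverse-CDF sampler from the discrete truncated power law
# P(x) propto x^-a on integers [xmin, xmax]; independent of the MLE code.
rtruncpow <- function(n, a, xmin, xmax) {
  support <- xmin:xmax
  p <- support^(-a)
  sample(support, n, replace = TRUE, prob = p / sum(p))
}

# Brute-force avalanche extraction by explicit scanning (oracle for the
# rle/cumsum implementation).
oracle_avalanches <- function(x) {
  sizes <- numeric(0); durs <- integer(0)
  cur_s <- 0; cur_d <- 0L
  for (v in c(x, 0)) {
    if (v != 0) {
      cur_s <- cur_s + v
      cur_d <- cur_d + 1L
    } else if (cur_d > 0L) {
      sizes <- c(sizes, cur_s); durs <- c(durs, cur_d)
      cur_s <- 0; cur_d <- 0L
    }
  }
  data.frame(size = sizes, duration = durs)
}
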
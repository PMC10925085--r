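#' Mean delayed pairwise correlation at one coarse-graining factor
#'
#' Coarse-grains each tracked neuron's spike train by `k`, then for every
#' ordered pair `(i, j)` with `i != j` computes the product-moment
#' correlation between neuron `i`'s series and neuron `j`'s series shifted
#' forward by one coarse bin (lag `k` time steps), and averages over pairs.
#' Pairs in which either lagged series is constant have an undefined
#' correlation and are excluded (their number is reported).
#'
#' At criticality the mean delayed correlation rises with `k` and
#' saturates; in strongly subcritical networks it stays near zero for all
#' `k`.
#'
#' @param raster a [simulate_raster()] object or a 0/1 (or count) matrix
#'   with one row per neuron and one column per time step.
#' @param k coarse-graining factor; the raster must span at least `2 k`
#'   steps.
#' @return List with `C_bar` (mean correlation, `NA` if no valid pairs),
#'   `n_pairs_valid`, `n_pairs_total`, `k`, `defined`.
#' @export
mean_delayed_correlation <- function(raster, k = 1) {
  m <- if (inherits(raster, "spike_raster")) raster_matrix(raster)
       else as.matrix(raster)
  M <- nrow(m)
  if (M < 2) stop("need at least 2 neurons")
  if (ncol(m) < 2 * k) stop("raster must span at least 2*k time steps")
  L <- ncol(m) %/% k
  # coarse-grain along time: M x L matrix of per-bin spike counts
  cg <- matrix(0, nrow = M, ncol = L)
  for (b in seq_len(k)) {
    cg <- cg + m[, seq(b, by = k, length.out = L), drop = FALSE]
  }
  A <- cg[, seq_len(L - 1), drop = FALSE]        # neuron i, bins 1..L-1
  B <- cg[, seq(2, L), drop = FALSE]             # neuron j, bins 2..L
  n <- L - 1
  total <- M * (M - 1)
  if (n < 2)
    return(list(C_bar = NA_real_, n_pairs_valid = 0L,
                n_pairs_total = total, k = k, defined = FALSE))
  sdA <- apply(A, 1, stats::sd)
  sdB <- apply(B, 1, stats::sd)
  okA <- sdA > 0
  okB <- sdB > 0
  Ac <- A - rowMeans(A)
  Bc <- B - rowMeans(B)
  cov <- tcrossprod(Ac, Bc) / (n - 1)            # cov[i, j] = cov(A_i, B_j)
  cc <- cov / outer(sdA, sdB)
  valid <- outer(okA, okB) & !diag(TRUE, M)
  nv <- sum(valid)
  if (nv == 0)
    return(list(C_bar = NA_real_, n_pairs_valid = 0L,
                n_pairs_total = total, k = k, defined = FALSE))
  list(C_bar = mean(cc[valid]), n_pairs_valid = as.integer(nv),
       n_pairs_total = total, k = k, defined = TRUE)
}

#' Mean delayed correlation curve over coarse-graining factors
#'
#' @param raster see [mean_delayed_correlation()].
#' @param k_grid coarse-graining factors (default `1:100`, clipped to the
#'   raster length).
#' @return Data frame `k`, `mean_corr`, `n_pairs_valid`.
#' @export
correlation_curve <- function(raster, k_grid = 1:100) {
  m <- if (inherits(raster, "spike_raster")) raster_matrix(raster)
       else as.matrix(raster)
  k_grid <- k_grid[2 * k_grid <= ncol(m)]
  rows <- lapply(k_grid, function(k) {
    r <- mean_delayed_correlation(m, k)
    data.frame(k = k, mean_corr = r$C_bar, n_pairs_valid = r$n_pairs_valid)
  })
  do.call(rbind, rows)
}
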
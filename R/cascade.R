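#' Temporal coarse-graining of an activity series
#'
#' Sums activity over non-overlapping windows of `k` consecutive bins
#' (half-open windows `[i*k, (i+1)*k)`, 0-based).  A trailing remainder of
#' fewer than `k` bins is dropped, so total activity is conserved up to the
#' dropped remainder.
#'
#' @param x numeric vector of non-negative activity per bin.
#' @param k integer coarse-graining factor (`>= 1`).
#' @return Numeric vector of length `floor(length(x) / k)`.
#' @examples
#' coarse_grain(c(1, 2, 3, 4, 5), 2)  # c(3, 7)
#' @export
coarse_grain <- function(x, k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k != round(k))
    stop("k must be a single integer >= 1")
  k <- as.integer(k)
  if (k == 1L) return(x)
  n <- (length(x) %/% k) * k
  if (n == 0L) return(x[0])
  .colSums(x[seq_len(n)], k, n %/% k)
}

#' Coincident-firing threshold
#'
#' Sets all bins with activity strictly below `theta` to zero; bins with
#' activity `>= theta` ("surpassing" the threshold) are kept unchanged.
#'
#' @param x numeric activity vector.
#' @param theta non-negative threshold.
#' @return Thresholded vector of the same length.
#' @examples
#' apply_threshold(c(0, 3, 5, 0, 2), 3)  # c(0, 3, 5, 0, 0)
#' @export
apply_threshold <- function(x, theta) {
  if (length(theta) != 1 || is.na(theta) || theta < 0)
    stop("theta must be a single non-negative number")
  x[x < theta] <- 0
  x
}

#' Extract avalanches from a thresholded series
#'
#' An avalanche is a maximal run of nonzero bins: its size `S` is the sum of
#' bin values over the run (inclusive convention: full suprathreshold bin
#' values, no baseline subtraction) and its duration `T` is the run length
#' in bins.  With `size_convention = "exclusive"` the threshold baseline
#' `theta` is subtracted from every bin before summing.
#'
#' @param x thresholded activity vector (zeros separate avalanches).
#' @param size_convention `"inclusive"` (default) or `"exclusive"`.
#' @param theta baseline used by the exclusive convention (default 0).
#' @return Data frame with columns `size` and `duration` (class
#'   `"avalanche_set"`), one row per avalanche.
#' @examples
#' extract_avalanches(c(0, 3, 5, 0, 0, 4, 0))  # sizes 8 and 4
#' @export
extract_avalanches <- function(x, size_convention = c("inclusive", "exclusive"),
                               theta = 0) {
  size_convention <- match.arg(size_convention)
  nz <- x != 0
  if (!any(nz)) {
    out <- data.frame(size = numeric(0), duration = integer(0))
    class(out) <- c("avalanche_set", "data.frame")
    return(out)
  }
  r <- rle(nz)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]; durs <- r$lengths[keep]
  cs <- cumsum(as.numeric(x))  # double accumulation: totals can exceed 2^31
  sizes <- cs[ends] - c(0, cs)[starts]
  if (size_convention == "exclusive") sizes <- sizes - theta * durs
  out <- data.frame(size = sizes, duration = as.integer(durs))
  class(out) <- c("avalanche_set", "data.frame")
  out
}

#' Full avalanche extraction pipeline
#'
#' Composes subsampling, temporal coarse-graining, thresholding and
#' avalanche extraction, pooling over simulation runs while never letting an
#' avalanche span a run boundary.  Accepts either an `"ei_simulation"`
#' object (using its coupled sampled trace for `f`, or the population
#' totals at `f = 1`), a list of activity vectors (one per run), or a
#' single numeric vector.
#'
#' On integer spike data a fractional threshold `theta < 1` is unobservable
#' (the model has 1-spike resolution): the pipeline then returns an empty
#' set flagged `unobservable`.
#'
#' @param x simulation, list of numeric vectors, or numeric vector.
#' @param f sampling fraction used to select the coupled trace (default 1).
#' @param k coarse-graining factor.
#' @param theta coincident-firing threshold.
#' @param size_convention see [extract_avalanches()].
#' @return An `"avalanche_set"` data frame with attributes `k`, `theta`,
#'   `f`, `unobservable`, and a `run_id` column.
#' @export
avalanche_pipeline <- function(x, f = 1, k = 1, theta = 0,
                               size_convention = "inclusive") {
  series <- pipeline_series(x, f)
  integer_data <- all(vapply(series, function(s) {
    length(s) == 0 || is.integer(s) || all(s == round(s))
  }, logical(1)))
  unobs <- integer_data && theta > 0 && theta < 1
  if (unobs) {
    out <- data.frame(size = numeric(0), duration = integer(0),
                      run_id = integer(0))
  } else {
    pieces <- lapply(seq_along(series), function(i) {
      av <- extract_avalanches(
        apply_threshold(coarse_grain(series[[i]], k), theta),
        size_convention = size_convention, theta = theta)
      if (nrow(av)) av$run_id <- i else av$run_id <- integer(0)
      av
    })
    out <- do.call(rbind, pieces)
  }
  class(out) <- c("avalanche_set", "data.frame")
  attr(out, "k") <- k
  attr(out, "theta") <- theta
  attr(out, "f") <- f
  attr(out, "unobservable") <- unobs
  out
}

# normalize pipeline input to a list of activity vectors
pipeline_series <- function(x, f = 1) {
  if (inherits(x, "ei_simulation")) {
    lapply(x$runs, function(run) {
      if (f == 1) {
        if ("1" %in% names(run$sampled)) run$sampled[["1"]]
        else activity(run)
      } else {
        key <- as.character(f)
        if (!key %in% names(run$sampled))
          stop("no coupled sampled trace for f = ", f,
               "; available: ", paste(names(run$sampled), collapse = ", "))
        run$sampled[[key]]
      }
    })
  } else if (is.list(x)) {
    lapply(x, as.numeric)
  } else {
    list(as.numeric(x))
  }
}
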
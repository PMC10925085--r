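#' Write / read a population trace as CSV
#'
#' Population traces use the documented header `t, nE, nI, n_drive`;
#' single activity series use `t, count`.  Counts are stored as integers
#' and round-trip losslessly.
#'
#' @param run a simulation run (list with `nE`, `nI`, `n_drive`) or, for
#'   [write_series()], a numeric vector.
#' @param path output file path.
#' @return `write_*` return `path` invisibly; `read_trace()` returns a
#'   list with `nE`, `nI`, `n_drive`; `read_series()` a numeric vector.
#'   Empty files yield zero-length series rather than an error.
#' @export
write_trace <- function(run, path) {
  df <- data.frame(t = seq_along(run$nE), nE = run$nE, nI = run$nI,
                   n_drive = run$n_drive)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0)
    return(list(nE = integer(0), nI = integer(0), n_drive = integer(0)))
  need <- c("t", "nE", "nI", "n_drive")
  if (!all(need %in% names(df)))
    stop("malformed trace header: expected columns ",
         paste(need, collapse = ", "))
  check_counts(df$nE, path); check_counts(df$nI, path)
  check_counts(df$n_drive, path)
  if (is.unsorted(df$t, strictly = TRUE))
    stop("non-monotone time column in ", path,
         " (first offending line ", which(diff(df$t) <= 0)[1] + 1, ")")
  list(nE = as.integer(df$nE), nI = as.integer(df$nI),
       n_drive = as.integer(df$n_drive))
}

#' @rdname write_trace
#' @param x numeric activity vector.
#' @export
write_series <- function(x, path) {
  utils::write.csv(data.frame(t = seq_along(x), count = x), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0) return(numeric(0))
  if (!all(c("t", "count") %in% names(df)))
    stop("malformed series header: expected columns t, count")
  check_counts(df$count, path)
  df$count
}

check_counts <- function(v, path) {
  bad <- which(!is.finite(v) | v < 0)
  if (length(bad))
    stop("negative or non-finite count in ", path, " at line ", bad[1] + 1)
  invisible(TRUE)
}

#' Write / read an avalanche set as CSV
#'
#' Columns: `size, duration, k, theta, f, run_id` (extraction parameters
#' repeated per row for provenance).
#'
#' @param av an avalanche set from [avalanche_pipeline()].
#' @param path file path.
#' @return `write_avalanches()` returns `path` invisibly;
#'   `read_avalanches()` an `"avalanche_set"` data frame with the
#'   extraction parameters restored as attributes.
#' @export
write_avalanches <- function(av, path) {
  df <- data.frame(size = av$size, duration = av$duration,
                   k = attr(av, "k") %||% NA,
                   theta = attr(av, "theta") %||% NA,
                   f = attr(av, "f") %||% NA,
                   run_id = if ("run_id" %in% names(av)) av$run_id else 1L)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_avalanches
#' @export
read_avalanches <- function(path) {
  df <- utils::read.csv(path)
  out <- data.frame(size = df$size, duration = as.integer(df$duration),
                    run_id = df$run_id)
  class(out) <- c("avalanche_set", "data.frame")
  if (nrow(df)) {
    attr(out, "k") <- df$k[1]
    attr(out, "theta") <- df$theta[1]
    attr(out, "f") <- df$f[1]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a spike raster as sparse event-list TSV
#'
#' Events are stored as `neuron_id<TAB>t` rows preceded by `#`-prefixed
#' metadata lines (`M`, `M_E`, `steps`, `seed`).
#'
#' @param raster a [simulate_raster()] object.
#' @param path file path.
#' @return `write_raster()` returns `path` invisibly; `read_raster()` a
#'   `"spike_raster"` (without the coupled population trace).
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# M: %d", raster$M),
               sprintf("# M_E: %d", raster$M_E),
               sprintf("# steps: %d", raster$steps),
               sprintf("# seed: %s", raster$seed %||% "NA"),
               "neuron_id\tt"), con)
  utils::write.table(raster$events, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), ":\\s*")[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  names(df) <- c("neuron", "t")
  structure(list(events = df, M = as.integer(meta$M),
                 M_E = as.integer(meta$M_E),
                 steps = as.integer(meta$steps),
                 counts = tabulate(df$t, nbins = as.integer(meta$steps)),
                 seed = suppressWarnings(as.integer(meta$seed))),
            class = "spike_raster")
}

#' Run a named analysis pipeline from a configuration
#'
#' Executes one of the package pipelines from a structured configuration
#' (a YAML file path or an equivalent named list).  The configuration must
#' contain a `pipeline` field naming one of `simulate`, `avalanches`,
#' `scaling`, `rescue_map`, `collapse`, `corr`, `synth`, `exp_map`, plus
#' the fields that pipeline requires; missing fields raise a validation
#' error naming them.  When `out_dir` is given, result tables are written
#' as CSV together with the resolved configuration (`config.yaml`), so
#' every output carries its provenance; identical configurations and seeds
#' give identical outputs.
#'
#' @param config YAML file path or named list.
#' @param out_dir optional output directory (created if missing).
#' @return The pipeline's in-memory result, invisibly when written to disk.
#' @export
run_from_config <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  need <- function(fields) {
    missing <- setdiff(fields, names(config))
    if (length(missing))
      stop("config validation error; missing field(s): ",
           paste(missing, collapse = ", "))
  }
  need("pipeline")
  if (!is.null(config$seed)) set.seed(config$seed)
  params <- do.call(make_params, config$params %||% list())
  result <- switch(
    config$pipeline,
    simulate = {
      need(c("steps"))
      simulate_network(params, steps = config$steps,
                       n_runs = config$n_runs %||% 1,
                       sample_fractions = unlist(config$fractions) %||% 1,
                       seed = config$seed)
    },
    avalanches = {
      need(c("input", "k", "theta"))
      x <- read_series(config$input)
      avalanche_pipeline(x, k = config$k, theta = config$theta,
                         f = config$f %||% 1)
    },
    scaling = {
      need("input")
      av <- read_avalanches(config$input)
      exponent_suite(av, mode = config$mode %||% "full")
    },
    rescue_map = {
      need(c("input", "k_grid", "theta_grid"))
      x <- read_series(config$input)
      rescue_map(x, f = config$f %||% 1, k_grid = unlist(config$k_grid),
                 theta_grid = unlist(config$theta_grid),
                 mode = config$mode %||% "full")
    },
    collapse = {
      need(c("steps", "fractions", "theta100"))
      sim <- simulate_network(params, steps = config$steps,
                              n_runs = config$n_runs %||% 1,
                              sample_fractions = unlist(config$fractions),
                              seed = config$seed)
      scan_collapse(sim, fractions = unlist(config$fractions),
                    theta100_set = unlist(config$theta100),
                    k_grid = unlist(config$k_grid %||% list(2^(0:6))))
    },
    corr = {
      need(c("M", "steps"))
      rast <- simulate_raster(params, M = config$M, steps = config$steps,
                              seed = config$seed)
      correlation_curve(rast, k_grid = unlist(config$k_grid %||% list(1:20)))
    },
    synth = {
      need("n_rec")
      generate_recordings(params, n_rec = config$n_rec,
                          duration_s = config$duration_s %||% 1800,
                          seed = config$seed)
    },
    exp_map = {
      need("n_rec")
      recs <- generate_recordings(params, n_rec = config$n_rec,
                                  duration_s = config$duration_s %||% 1800,
                                  seed = config$seed)
      zscored_chi_map(recs,
                      z_grid = unlist(config$z_grid %||% list(seq(-2, 1.5, 0.5))),
                      k_grid = unlist(config$k_grid %||% list(c(1, 2, 4, 8))))
    },
    stop("unknown pipeline: ", config$pipeline)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
    if (is.data.frame(result)) {
      utils::write.csv(result, file.path(out_dir, "result.csv"),
                       row.names = FALSE)
    } else if (inherits(result, "collapse_scan")) {
      utils::write.csv(result$profile, file.path(out_dir, "result.csv"),
                       row.names = FALSE)
    } else if (inherits(result, "ei_simulation")) {
      for (r in seq_along(result$runs))
        write_trace(result$runs[[r]],
                    file.path(out_dir, sprintf("trace_run%03d.csv", r)))
    }
    return(invisible(result))
  }
  result
}
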
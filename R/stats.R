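#' Per-timepoint replicate statistics
#'
#' The building blocks of the per-run summary: arithmetic mean, sample
#' variance (denominator `m - 1`), coefficient of variation (standard
#' deviation over mean), and sample covariance between two time points
#' across replicates paired by index (the same vessel followed over time).
#'
#' @param x,y Numeric vectors of replicate observations at one time point
#'   (percent released). `x` and `y` must be the same length for
#'   [run_covariance()].
#' @return A single numeric value.
#' @examples
#' run_mean(c(2, 4, 6))        # 4
#' run_variance(c(2, 4, 6))    # 4
#' run_cv(c(1, 3))             # sqrt(2) / 2
#' run_covariance(c(1, 3), c(3, 1))  # -2
#' @export
run_mean <- function(x) {
  check_replicates(x, min_m = 1)
  mean(x)
}

#' @rdname run_mean
#' @export
run_variance <- function(x) {
  check_replicates(x, min_m = 2)
  stats::var(x)
}

#' @rdname run_mean
#' @export
run_cv <- function(x) {
  check_replicates(x, min_m = 2)
  m <- mean(x)
  if (m == 0) {
    abort("coefficient of variation is undefined for zero mean",
          class = "releaseopt_undefined_cv")
  }
  stats::sd(x) / m
}

#' @rdname run_mean
#' @export
run_covariance <- function(x, y) {
  check_replicates(x, min_m = 2)
  check_replicates(y, min_m = 2)
  if (length(x) != length(y)) {
    abort("replicate vectors must have equal length (replicates are paired)",
          class = "releaseopt_pairing_error")
  }
  stats::cov(x, y)
}

check_replicates <- function(x, min_m) {
  if (!is.numeric(x) || length(x) < min_m) {
    abort(sprintf("need at least %d replicate observation(s)", min_m),
          class = "releaseopt_insufficient_replicates")
  }
  if (any(!is.finite(x))) {
    abort("replicate observations must be finite",
          class = "releaseopt_invalid_value")
  }
  invisible(x)
}

#' Summarize a replicated dissolution design table
#'
#' Takes the long-format design table of a replicated dissolution
#' experiment -- for each run (factor-level combination), each profile time
#' point, and each replicate, one observed percent released -- and computes
#' the per-run summary statistics that the response surfaces are later
#' fitted to: mean, sample variance and coefficient of variation per time
#' point, and the sample covariance across replicates for every time-point
#' pair.
#'
#' Replicates are paired across time points by their replicate index, so
#' every run must observe the same time points with the same replicate ids;
#' incomplete tables are rejected rather than imputed.
#'
#' @param data A data frame with columns `run`, `timepoint`, `replicate`,
#'   `value`, plus one numeric column per coded factor.
#' @param factors Character vector naming the coded-factor columns. Default:
#'   every column other than the four structural ones.
#' @return An object of class `run_summary`: a list with tibbles
#'   `settings` (run, coded factor columns), `stats` (run, timepoint, m,
#'   mean, var, cv) and `covariances` (run, timepoint_i, timepoint_j, cov
#'   for `i < j` pairs).
#' @examples
#' d <- tidyr::expand_grid(run = 1:2, timepoint = c("y1", "y2"),
#'                         replicate = 1:3)
#' d$x1 <- ifelse(d$run == 1, -1, 1)
#' d$value <- 30 + 5 * d$x1 + (d$replicate - 2)
#' summarize_runs(d)
#' @export
summarize_runs <- function(data, factors = NULL) {
  data <- as_tibble(data)
  structural <- c("run", "timepoint", "replicate", "value")
  missing <- setdiff(structural, names(data))
  if (length(missing) > 0) {
    abort(paste0("design table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "releaseopt_schema_error")
  }
  factors <- factors %||% setdiff(names(data), structural)
  if (length(factors) == 0) {
    abort("design table has no factor columns",
          class = "releaseopt_schema_error")
  }
  if (!all(vapply(data[factors], is.numeric, logical(1)))) {
    abort("factor columns must be numeric (coded units)",
          class = "releaseopt_schema_error")
  }
  if (any(!is.finite(data$value))) {
    abort("observations must be finite", class = "releaseopt_invalid_value")
  }
  check_design_complete(data, factors)

  settings <- dplyr::distinct(data[c("run", factors)])
  settings <- dplyr::arrange(settings, .data$run)

  stats_tbl <- data |>
    dplyr::group_by(.data$run, .data$timepoint) |>
    dplyr::summarise(
      m = dplyr::n(),
      mean = run_mean(.data$value),
      var = run_variance(.data$value),
      cv = run_cv(.data$value),
      .groups = "drop"
    )

  tps <- unique(data$timepoint)
  pairs <- if (length(tps) >= 2) {
    as_tibble(t(utils::combn(tps, 2)), .name_repair = ~c("timepoint_i",
                                                         "timepoint_j"))
  } else {
    tibble(timepoint_i = character(0), timepoint_j = character(0))
  }
  wide <- data |>
    dplyr::arrange(.data$run, .data$replicate) |>
    tidyr::pivot_wider(id_cols = c("run", "replicate"),
                       names_from = "timepoint", values_from = "value")
  covariances <- tidyr::expand_grid(run = settings$run, pairs)
  if (nrow(covariances) > 0) {
    covariances$cov <- purrr::pmap_dbl(covariances, function(run, timepoint_i,
                                                             timepoint_j) {
      block <- wide[wide$run == run, ]
      run_covariance(block[[timepoint_i]], block[[timepoint_j]])
    })
  } else {
    covariances$cov <- numeric(0)
  }

  structure(
    list(settings = settings, stats = stats_tbl, covariances = covariances,
         factors = factors, timepoints = tps),
    class = "run_summary"
  )
}

check_design_complete <- function(data, factors) {
  counts <- dplyr::count(data, .data$run, .data$timepoint)
  if (length(unique(counts$n)) != 1) {
    abort("every run/timepoint cell needs the same number of replicates",
          class = "releaseopt_schema_error")
  }
  if (counts$n[1] < 2) {
    abort("at least 2 replicates per run/timepoint are required",
          class = "releaseopt_insufficient_replicates")
  }
  cells <- dplyr::count(dplyr::distinct(
    data[c("run", "timepoint", "replicate")]), .data$run, .data$timepoint)
  if (any(cells$n != counts$n[1])) {
    abort("replicate ids must be unique within each run/timepoint cell",
          class = "releaseopt_schema_error")
  }
  per_run_tp <- dplyr::distinct(data[c("run", "timepoint")])
  tp_per_run <- dplyr::count(per_run_tp, .data$run)
  if (length(unique(tp_per_run$n)) != 1 ||
      tp_per_run$n[1] != length(unique(data$timepoint))) {
    abort("every run must observe the same set of time points",
          class = "releaseopt_schema_error")
  }
  fac_per_run <- dplyr::count(dplyr::distinct(data[c("run", factors)]),
                              .data$run)
  if (any(fac_per_run$n != 1)) {
    abort("factor settings must be constant within a run",
          class = "releaseopt_schema_error")
  }
  invisible(data)
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("<run_summary> %d run(s) x %d timepoint(s), m = %d replicates\n",
              nrow(x$settings), length(x$timepoints), x$stats$m[1]))
  print(x$stats, n = 10)
  invisible(x)
}

#' @rdname summarize_runs
#' @param x A `run_summary` object.
#' @param ... Unused.
#' @export
tidy.run_summary <- function(x, ...) {
  moments <- x$stats |>
    tidyr::pivot_longer(c("mean", "var", "cv"),
                        names_to = "statistic", values_to = "value") |>
    dplyr::transmute(.data$run, statistic = .data$statistic,
                     timepoint_i = .data$timepoint,
                     timepoint_j = NA_character_, value = .data$value)
  covs <- dplyr::transmute(x$covariances, .data$run, statistic = "cov",
                           .data$timepoint_i, .data$timepoint_j,
                           value = .data$cov)
  dplyr::bind_rows(moments, covs)
}

#' Read and write design tables as CSV
#'
#' The on-disk dialect is the same long format [summarize_runs()] consumes:
#' columns `run`, coded factor columns, `timepoint`, `replicate`, `value`.
#'
#' @param path CSV file path.
#' @param data A design table.
#' @param factors Optional character vector of factor column names used for
#'   validation on read.
#' @return `read_design_table()` returns a validated tibble;
#'   `write_design_table()` returns `path` invisibly.
#' @export
read_design_table <- function(path, factors = NULL) {
  if (!file.exists(path)) {
    abort(paste0("no such design table: ", path),
          class = "releaseopt_schema_error")
  }
  data <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  structural <- c("run", "timepoint", "replicate", "value")
  missing <- setdiff(structural, names(data))
  if (length(missing) > 0) {
    abort(paste0("design table CSV is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "releaseopt_schema_error")
  }
  factors <- factors %||% setdiff(names(data), structural)
  check_design_complete(data, factors)
  data
}

#' @rdname read_design_table
#' @export
write_design_table <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}
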
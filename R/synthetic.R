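#' Specify a synthetic replicated dissolution experiment
#'
#' Defines the ground truth for a simulated study: true mean surfaces per
#' time point, an inter-timepoint replicate covariance matrix, the coded
#' design, and the replicate count. [generate_experiment()] then draws each
#' run's replicates as multivariate normal vectors across time points --
#' emulating the same vessel sampled repeatedly over time, so replicate
#' noise can be correlated between time points.
#'
#' @param mean_surfaces Named list of `response_surface`s, one per time
#'   point; names become the timepoint labels.
#' @param design Matrix or data frame of coded factor settings, one row
#'   per run, columns named by factor.
#' @param sigma Replicate covariance across time points: a symmetric
#'   positive semi-definite matrix (timepoints x timepoints), a vector of
#'   per-timepoint variances, or a single variance.
#' @param m Replicates per run, at least 2 (default 3, a typical
#'   dissolution-bath vessel count per setting).
#' @param seed Integer seed making the draw reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(mean_surfaces, design, sigma = 1, m = 3,
                           seed = 1L) {
  if (is.null(names(mean_surfaces)) || any(names(mean_surfaces) == "")) {
    abort("mean_surfaces must be a named list (names = timepoint labels)",
          class = "releaseopt_schema_error")
  }
  stopifnot(all(vapply(mean_surfaces, inherits, logical(1),
                       "response_surface")))
  design <- as_setting_matrix(design)
  w <- length(mean_surfaces)
  if (!is.matrix(sigma)) {
    sigma <- diag(rep(sigma, length.out = w), nrow = w)
  }
  if (!isSymmetric(unname(sigma)) || nrow(sigma) != w) {
    abort("sigma must be a symmetric timepoints x timepoints matrix",
          class = "releaseopt_schema_error")
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    abort("sigma must be positive semi-definite",
          class = "releaseopt_schema_error")
  }
  if (m < 2) {
    abort("at least 2 replicates are required",
          class = "releaseopt_insufficient_replicates")
  }
  structure(
    list(mean_surfaces = mean_surfaces, design = design, sigma = sigma,
         m = as.integer(m), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Draw a synthetic replicated design table
#'
#' @param spec A [synthetic_spec()].
#' @return A long-format design table tibble (columns `run`, coded factor
#'   columns, `timepoint`, `replicate`, `value`) ready for
#'   [summarize_runs()]. The same spec (including seed) always yields the
#'   identical table.
#' @examples
#' truth <- response_surface(c("1" = 30, x1 = 5), "mean", "y1")
#' spec <- synthetic_spec(list(y1 = truth), cbind(x1 = c(-1, 0, 1)),
#'                        sigma = 0.5, m = 3, seed = 42)
#' generate_experiment(spec)
#' @export
generate_experiment <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  labels <- names(spec$mean_surfaces)
  n <- nrow(spec$design)
  w <- length(labels)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  mu <- vapply(spec$mean_surfaces, evaluate_surface, numeric(n),
               points = spec$design)
  mu <- matrix(mu, nrow = n, dimnames = list(NULL, labels))

  blocks <- purrr::map_dfr(seq_len(n), function(r) {
    draws <- if (all(spec$sigma == 0)) {
      matrix(rep(mu[r, ], each = spec$m), nrow = spec$m,
             dimnames = list(NULL, labels))
    } else {
      d <- MASS::mvrnorm(spec$m, mu = mu[r, ], Sigma = spec$sigma)
      matrix(d, nrow = spec$m, dimnames = list(NULL, labels))
    }
    fac <- as_tibble(as.data.frame(
      spec$design[rep(r, spec$m * w), , drop = FALSE]))
    dplyr::bind_cols(
      tibble(run = r),
      fac,
      tibble(
        timepoint = rep(labels, each = spec$m),
        replicate = rep(seq_len(spec$m), times = w),
        value = as.numeric(draws)
      )
    )
  })
  blocks
}
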
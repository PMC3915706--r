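#' Dissolution profile comparison indices f1 and f2
#'
#' The regulatory dissimilarity factor
#' `f1 = 100 * sum(|R - T|) / sum(R)` and similarity factor
#' `f2 = 50 * log10(100 * (1 + mean((R - T)^2))^(-1/2))`, comparing a test
#' release profile against a reference over the same time points. Identical
#' profiles give `f1 = 0` and `f2 = 100`; f2 decreases as the profiles
#' separate (f2 >= 50 is the conventional similarity criterion).
#'
#' f1 uses absolute differences so it is a true magnitude of dissimilarity,
#' and f2 places the factor 100 inside the logarithm so that identical
#' profiles score exactly 100; these are the standard regulatory forms.
#'
#' @param reference,test Numeric vectors of percent released at the same
#'   time points.
#' @return A single numeric value.
#' @examples
#' f1_index(c(10, 20), c(9, 18))   # 10
#' f2_index(c(30, 60), c(30, 60))  # 100
#' @export
f1_index <- function(reference, test) {
  check_profile_pair(reference, test)
  s <- sum(reference)
  if (s == 0) {
    abort("f1 is undefined when the reference profile sums to zero",
          class = "releaseopt_undefined_index")
  }
  100 * sum(abs(reference - test)) / s
}

#' @rdname f1_index
#' @export
f2_index <- function(reference, test) {
  check_profile_pair(reference, test)
  msd <- mean((reference - test)^2)
  50 * log10(100 / sqrt(1 + msd))
}

check_profile_pair <- function(reference, test) {
  if (length(reference) != length(test)) {
    abort("reference and test profiles must cover the same time points",
          class = "releaseopt_pairing_error")
  }
  if (length(reference) < 1) {
    abort("profiles must contain at least one time point",
          class = "releaseopt_invalid_value")
  }
  if (any(!is.finite(reference)) || any(!is.finite(test))) {
    abort("profile values must be finite", class = "releaseopt_invalid_value")
  }
  invisible(TRUE)
}

#' Mean-squared-error profile objective
#'
#' The competing optimization criterion that ignores specification limits:
#' the sum over time points of the squared deviation of the fitted mean
#' from its target plus the fitted variance,
#' `sum_q (mu_q(x) - T_q)^2 + sum_q v_q(x)`. Smaller is better; zero means
#' every mean hits its target with zero predicted variance.
#'
#' @param points A named coded point or matrix of points.
#' @param mean_surfaces,var_surfaces Lists of `response_surface` objects,
#'   aligned with `targets`. `var_surfaces` may be `NULL` when only means
#'   are modeled.
#' @param targets Numeric vector of target values, one per mean surface.
#' @return Numeric vector of objective values, one per point.
#' @export
mse_objective <- function(points, mean_surfaces, var_surfaces = NULL,
                          targets) {
  pts <- as_setting_matrix(points)
  if (length(mean_surfaces) != length(targets)) {
    abort("need one target per mean surface",
          class = "releaseopt_invalid_value")
  }
  if (!is.null(var_surfaces) &&
      length(var_surfaces) != length(mean_surfaces)) {
    abort("need one variance surface per mean surface (or NULL)",
          class = "releaseopt_invalid_value")
  }
  out <- numeric(nrow(pts))
  for (q in seq_along(mean_surfaces)) {
    out <- out + (evaluate_surface(mean_surfaces[[q]], pts) - targets[q])^2
    if (!is.null(var_surfaces)) {
      out <- out + evaluate_surface(var_surfaces[[q]], pts)
    }
  }
  out
}
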
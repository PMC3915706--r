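#' Derringer-Suich individual desirability functions
#'
#' Map a response value to a desirability in \[0, 1\]:
#'
#' * `d_ntb()` -- nominal-the-best: 1 at the target, power-`r` ramp up from
#'   the lower specification limit, power-`s` ramp down to the upper limit,
#'   0 outside \[`lsl`, `usl`\].
#' * `d_ltb()` -- larger-the-better: 0 at or below `lower` (lowest
#'   acceptable), 1 at or above `upper` (ideal), power-`r` ramp between.
#' * `d_stb()` -- smaller-the-better: the mirror image, 1 at or below
#'   `lower` (ideal), 0 at or above `upper` (highest acceptable).
#'
#' All three are vectorized over `y`.
#'
#' @param y Numeric vector of response values.
#' @param lsl,target,usl NTB specification limits, `lsl < target < usl`.
#' @param lower,upper LTB/STB bounds, `lower < upper`.
#' @param r,s Positive shape exponents (1 = linear ramps).
#' @return Numeric vector of desirabilities in \[0, 1\].
#' @examples
#' d_ntb(25, lsl = 20, target = 30, usl = 40)  # 0.5
#' d_ltb(75, lower = 50, upper = 100)          # 0.5
#' d_stb(0, lower = 0, upper = 10)             # 1
#' @export
d_ntb <- function(y, lsl, target, usl, r = 1, s = 1) {
  check_desirability_spec(lsl < target && target < usl, r, s)
  d <- numeric(length(y))
  up <- y > lsl & y <= target
  down <- y > target & y < usl
  d[up] <- ((y[up] - lsl) / (target - lsl))^r
  d[down] <- ((y[down] - usl) / (target - usl))^s
  d[!is.finite(y)] <- 0
  d
}

#' @rdname d_ntb
#' @export
d_ltb <- function(y, lower, upper, r = 1) {
  check_desirability_spec(lower < upper, r)
  d <- numeric(length(y))
  d[y >= upper] <- 1
  mid <- y > lower & y < upper
  d[mid] <- ((y[mid] - lower) / (upper - lower))^r
  d[!is.finite(y)] <- 0
  d
}

#' @rdname d_ntb
#' @export
d_stb <- function(y, lower, upper, r = 1) {
  check_desirability_spec(lower < upper, r)
  d <- numeric(length(y))
  d[y <= lower] <- 1
  mid <- y > lower & y < upper
  d[mid] <- ((upper - y[mid]) / (upper - lower))^r
  d[!is.finite(y)] <- 0
  d
}

check_desirability_spec <- function(ordered, r, s = 1) {
  if (!isTRUE(ordered)) {
    abort("desirability bounds must be strictly ordered",
          class = "releaseopt_schema_error")
  }
  if (!(r > 0) || !(s > 0)) {
    abort("desirability exponents must be positive",
          class = "releaseopt_schema_error")
  }
  invisible(TRUE)
}

#' Assemble a composite desirability specification
#'
#' A composite specification is a tibble with one row per scored component:
#' which surface to evaluate, how to turn its value into an individual
#' desirability, and its weight in the weighted geometric mean. Negative
#' fitted values of intrinsically nonnegative statistics (variance, cv) are
#' clamped to zero before scoring, with a warning.
#'
#' @param surface Character vector of surface names (into a `surface_set`
#'   or fixture surface list).
#' @param kind `"NTB"`, `"LTB"` or `"STB"` per component.
#' @param lsl,target,usl Bounds per component. For NTB all three; for
#'   LTB/STB, `lsl`/`usl` are the lower/upper bounds of the ramp
#'   (`target` ignored).
#' @param weight Nonnegative component weights.
#' @param r,s Shape exponents.
#' @param clamp Should negative surface values be clamped to 0 before
#'   scoring (used for variance/cv components)?
#' @return A tibble of class `composite_spec`.
#' @export
composite_spec <- function(surface, kind, lsl = NA_real_, target = NA_real_,
                           usl = NA_real_, weight = 1, r = 1, s = 1,
                           clamp = FALSE) {
  out <- tibble(
    surface = as.character(surface), kind = as.character(kind),
    lsl = as.numeric(lsl), target = as.numeric(target),
    usl = as.numeric(usl), weight = as.numeric(weight),
    r = as.numeric(r), s = as.numeric(s), clamp = as.logical(clamp)
  )
  if (any(out$weight < 0) || any(!is.finite(out$weight))) {
    abort("component weights must be finite and nonnegative",
          class = "releaseopt_schema_error")
  }
  if (all(out$weight == 0)) {
    abort("at least one component weight must be positive",
          class = "releaseopt_schema_error")
  }
  class(out) <- c("composite_spec", class(out))
  out
}

# Individual desirability of component i of a spec at response values y.
component_desirability <- function(spec_row, y) {
  if (isTRUE(spec_row$clamp)) {
    if (any(y < 0)) {
      warn(paste0("negative fitted ", spec_row$surface,
                  " clamped to 0 before desirability scoring"),
           class = "releaseopt_clamp_warning")
    }
    y <- pmax(y, 0)
  }
  switch(spec_row$kind,
    NTB = d_ntb(y, spec_row$lsl, spec_row$target, spec_row$usl,
                spec_row$r, spec_row$s),
    LTB = d_ltb(y, spec_row$lsl, spec_row$usl, spec_row$r),
    STB = d_stb(y, spec_row$lsl, spec_row$usl, spec_row$r),
    abort(paste0("unknown component kind: ", spec_row$kind),
          class = "releaseopt_schema_error")
  )
}

#' Composite desirability at coded points
#'
#' The composite objective is the weighted geometric mean of the individual
#' component desirabilities,
#' `D = (prod d_i^w_i)^(1 / sum w_i)`, computed via the sum of
#' `w_i * log(d_i)` with `log(0)` treated as `-Inf` (so any
#' positively-weighted component at 0 annihilates the composite; no epsilon
#' flooring). Components with weight 0 are ignored. Multiplying all weights
#' by a positive constant leaves the composite unchanged.
#'
#' @param points A named coded point or a matrix/data frame of points.
#' @param surfaces A named list of `response_surface` objects (e.g. a
#'   `surface_set` or a fixture's surfaces).
#' @param spec A [composite_spec()] whose `surface` column indexes into
#'   `surfaces`.
#' @return For a single point, a list with `value` and a `breakdown` tibble
#'   (component, response value, desirability, weight); for multiple
#'   points, a numeric vector of composite values.
#' @export
composite_desirability <- function(points, surfaces, spec) {
  pts <- as_setting_matrix(points)
  res <- composite_matrix(pts, surfaces, spec)
  if (nrow(pts) > 1) return(res$value)
  list(
    value = res$value,
    breakdown = tibble(
      component = spec$surface, kind = spec$kind,
      value = unname(drop(res$values)),
      desirability = unname(drop(res$desirabilities)),
      weight = spec$weight
    )
  )
}

# Vectorized core: returns list(value = numeric(n), values, desirabilities).
composite_matrix <- function(pts, surfaces, spec) {
  stopifnot(inherits(spec, "composite_spec") || is.data.frame(spec))
  missing <- setdiff(spec$surface, names(surfaces))
  if (length(missing) > 0) {
    abort(paste0("composite spec references unknown surface(s): ",
                 paste(missing, collapse = ", ")),
          class = "releaseopt_schema_error")
  }
  active <- which(spec$weight > 0)
  if (length(active) == 0) {
    abort("all component weights are zero", class = "releaseopt_schema_error")
  }
  n <- nrow(pts)
  values <- matrix(NA_real_, n, nrow(spec),
                   dimnames = list(NULL, spec$surface))
  desir <- matrix(NA_real_, n, nrow(spec),
                  dimnames = list(NULL, spec$surface))
  logsum <- numeric(n)
  wsum <- sum(spec$weight[active])
  for (i in seq_len(nrow(spec))) {
    yv <- evaluate_surface(surfaces[[spec$surface[i]]], pts)
    values[, i] <- yv
    di <- component_desirability(spec[i, ], yv)
    desir[, i] <- di
    if (spec$weight[i] > 0) {
      logsum <- logsum + spec$weight[i] * ifelse(di > 0, log(di), -Inf)
    }
  }
  list(value = exp(logsum / wsum), values = values, desirabilities = desir)
}
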
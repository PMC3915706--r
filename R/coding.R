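#' Define controllable formulation factors
#'
#' A factor table describes the controllable variables of a dissolution
#' study: the natural-unit levels used in the experiment and the linear
#' coding transform `coded = (natural - center) / scale` under which all
#' modeling and optimization is carried out. Centers and scales are stored
#' explicitly rather than derived from the levels, because published codings
#' are not always midpoint/half-range.
#'
#' @param name Character vector of factor identifiers (e.g. `"x1"`).
#' @param center Numeric vector of coding centers, natural units.
#' @param scale Numeric vector of positive coding scales, natural units.
#' @param levels List of numeric vectors, the natural-unit design levels of
#'   each factor (at least two distinct values each).
#' @param label Optional character vector of human-readable descriptions.
#' @param unit Optional character vector of natural units (annotation only;
#'   coded values are dimensionless).
#'
#' @return A tibble with one row per factor and columns `name`, `label`,
#'   `unit`, `center`, `scale`, `levels` (list-column).
#' @examples
#' factor_table(
#'   name = c("x1", "x2"),
#'   center = c(1000, 10), scale = c(500, 5),
#'   levels = list(c(500, 1000, 1500), c(5, 10, 15)),
#'   unit = c("rpm", "%")
#' )
#' @export
factor_table <- function(name, center, scale, levels,
                         label = name, unit = NA_character_) {
  if (!is.list(levels)) levels <- list(levels)
  out <- tibble(
    name = as.character(name),
    label = as.character(label),
    unit = as.character(unit),
    center = as.numeric(center),
    scale = as.numeric(scale),
    levels = levels
  )
  validate_factor_table(out)
}

validate_factor_table <- function(factors) {
  stopifnot(is.data.frame(factors))
  required <- c("name", "center", "scale", "levels")
  missing <- setdiff(required, names(factors))
  if (length(missing) > 0) {
    abort(paste0("factor table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "releaseopt_schema_error")
  }
  if (anyDuplicated(factors$name)) {
    abort("factor names must be unique", class = "releaseopt_schema_error")
  }
  if (any(!is.finite(factors$scale)) || any(factors$scale <= 0)) {
    abort("factor coding scales must be positive and finite",
          class = "releaseopt_invalid_value")
  }
  if (any(!is.finite(factors$center))) {
    abort("factor coding centers must be finite",
          class = "releaseopt_invalid_value")
  }
  ok <- vapply(factors$levels, function(l) {
    is.numeric(l) && all(is.finite(l)) && length(unique(l)) >= 2
  }, logical(1))
  if (any(!ok)) {
    abort(paste0("each factor needs >= 2 distinct finite levels; offending: ",
                 paste(factors$name[!ok], collapse = ", ")),
          class = "releaseopt_schema_error")
  }
  as_tibble(factors)
}

#' Code and decode factor values
#'
#' `code_value()` maps natural-unit values to dimensionless coded units via
#' `(natural - center) / scale`; `decode_value()` is the exact inverse.
#' Both are vectorized over values, and over factors when `value` has one
#' element per factor row.
#'
#' @param factors A factor table (see [factor_table()]), or a single row of
#'   one.
#' @param value Numeric vector of values to transform. Either one value per
#'   factor row (transformed pairwise) or, when `factors` has a single row,
#'   any length.
#' @param name Optional factor name selecting one row of `factors`.
#'
#' @return Numeric vector of transformed values, named by factor when
#'   transforming one value per factor.
#' @examples
#' f <- factor_table("x1", center = 1000, scale = 500,
#'                   levels = list(c(500, 1000, 1500)))
#' code_value(f, 1500)    # 1
#' decode_value(f, -0.7576)  # 621.2
#' @export
code_value <- function(factors, value, name = NULL) {
  transform_value(factors, value, name, direction = "code")
}

#' @rdname code_value
#' @export
decode_value <- function(factors, value, name = NULL) {
  transform_value(factors, value, name, direction = "decode")
}

transform_value <- function(factors, value, name, direction) {
  factors <- validate_factor_table(factors)
  if (!is.null(name)) {
    factors <- factors[factors$name %in% name, , drop = FALSE]
    if (nrow(factors) == 0) {
      abort(paste0("unknown factor: ", paste(name, collapse = ", ")),
            class = "releaseopt_unknown_factor")
    }
  }
  if (!is.numeric(value) || any(!is.finite(value))) {
    abort("values to transform must be finite numerics",
          class = "releaseopt_invalid_value")
  }
  if (nrow(factors) == 1) {
    out <- switch(direction,
      code = (value - factors$center) / factors$scale,
      decode = value * factors$scale + factors$center
    )
    if (length(out) == 1) names(out) <- factors$name
    return(out)
  }
  if (length(value) != nrow(factors)) {
    abort(sprintf("expected %d values (one per factor), got %d",
                  nrow(factors), length(value)),
          class = "releaseopt_invalid_value")
  }
  out <- switch(direction,
    code = (value - factors$center) / factors$scale,
    decode = value * factors$scale + factors$center
  )
  setNames(out, factors$name)
}

#' Coded design levels of each factor
#'
#' @param factors A factor table.
#' @return A list (named by factor) of coded level vectors.
#' @export
coded_levels <- function(factors) {
  factors <- validate_factor_table(factors)
  out <- purrr::map2(factors$levels, seq_len(nrow(factors)), function(l, i) {
    (l - factors$center[i]) / factors$scale[i]
  })
  setNames(out, factors$name)
}

#' All coded factorial design points
#'
#' Crosses the coded levels of every factor into the full factorial grid of
#' candidate design points, used e.g. to calibrate dispersion desirability
#' bounds.
#'
#' @param factors A factor table.
#' @param max_points Safety cap on the number of crossed points; factors
#'   with many levels are thinned evenly before crossing if the full cross
#'   would exceed it.
#' @return A numeric matrix, one row per design point, columns named by
#'   factor.
#' @export
design_points <- function(factors, max_points = 100000) {
  lv <- coded_levels(factors)
  n_total <- prod(vapply(lv, length, numeric(1)))
  while (n_total > max_points) {
    longest <- which.max(vapply(lv, length, integer(1)))
    l <- lv[[longest]]
    keep <- unique(round(seq(1, length(l), length.out = length(l) - 1)))
    lv[[longest]] <- l[keep]
    n_total <- prod(vapply(lv, length, numeric(1)))
  }
  grid <- do.call(expand.grid, c(lv, KEEP.OUT.ATTRS = FALSE))
  as.matrix(grid)
}
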
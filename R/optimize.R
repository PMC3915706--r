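#' Deterministic box-constrained optimization by grid scan plus polish
#'
#' Maximizes (or minimizes) a vectorized objective over a rectangular box
#' of coded factor settings: a dense axis-aligned grid scan locates the
#' best cell, then a bounded quasi-Newton polish (`optim` L-BFGS-B) refines
#' it, optionally from several of the best grid cells. Every step is
#' deterministic, so repeated runs with the same configuration are
#' bit-identical; ties on the grid break to the lexicographically smallest
#' coded point. The reported optimum never falls below the grid maximum.
#'
#' @param objective Function taking a matrix of coded points (one row per
#'   point, columns named by factor) and returning a numeric vector of
#'   objective values.
#' @param box Tibble/data frame with columns `name`, `lower`, `upper`.
#' @param n_grid Grid points per axis. Default: 41 for up to 3 factors, 11
#'   for 4-5, 7 above.
#' @param maximize Maximize (default) or minimize.
#' @param polish Run the local polish after the grid scan?
#' @param n_starts Number of best distinct grid cells to polish from.
#' @return An `optimization_result` with elements `par` (named coded
#'   optimum), `value`, `grid_value`, `trace` and the `objective` itself.
#' @examples
#' box <- tibble::tibble(name = "x1", lower = -1, upper = 1)
#' f <- function(p) -(p[, "x1"] - 0.3)^2
#' optimize_profile(f, box)$par
#' @export
optimize_profile <- function(objective, box, n_grid = NULL, maximize = TRUE,
                             polish = TRUE, n_starts = 1) {
  box <- as_tibble(box)
  stopifnot(all(c("name", "lower", "upper") %in% names(box)),
            all(box$lower < box$upper))
  k <- nrow(box)
  n_grid <- n_grid %||% default_grid_resolution(k)
  axes <- purrr::map2(box$lower, box$upper, ~seq(.x, .y, length.out = n_grid))
  names(axes) <- box$name
  grid <- as.matrix(do.call(expand.grid, c(axes, KEEP.OUT.ATTRS = FALSE)))
  vals <- objective(grid)
  if (!is.numeric(vals) || length(vals) != nrow(grid)) {
    abort("objective must return one value per point",
          class = "releaseopt_invalid_value")
  }
  sign <- if (maximize) 1 else -1
  svals <- sign * vals
  finite <- is.finite(svals)
  if (!any(finite) || (maximize && max(svals[finite]) <= 0 &&
                       all(svals[finite] == 0))) {
    abort(paste0("objective is ", if (maximize) "zero" else "non-finite",
                 " everywhere on the grid; no feasible optimum"),
          class = "releaseopt_infeasible")
  }
  best_val <- max(svals[finite])
  ties <- which(svals == best_val)
  ord <- do.call(order, as.data.frame(grid[ties, , drop = FALSE]))
  best_idx <- ties[ord[1]]
  grid_par <- grid[best_idx, ]
  grid_value <- vals[best_idx]

  par <- grid_par
  value <- grid_value
  polish_info <- NULL
  if (polish) {
    starts <- polish_starts(grid, svals, n_starts)
    for (s in starts) {
      fn <- function(p) {
        v <- objective(matrix(p, nrow = 1, dimnames = list(NULL, box$name)))
        if (!is.finite(v)) return(sign * -1e30)
        v
      }
      fit <- tryCatch(
        optim(grid[s, ], fn, method = "L-BFGS-B",
              lower = box$lower, upper = box$upper,
              control = list(fnscale = -sign, maxit = 200)),
        error = function(e) NULL
      )
      if (!is.null(fit)) {
        cand <- pmin(pmax(fit$par, box$lower), box$upper)
        cand_val <- objective(matrix(cand, nrow = 1,
                                     dimnames = list(NULL, box$name)))
        if (is.finite(cand_val) && sign * cand_val > sign * value) {
          par <- setNames(cand, box$name)
          value <- cand_val
        }
      }
    }
    polish_info <- list(method = "L-BFGS-B", n_starts = length(starts))
  }
  structure(
    list(
      par = setNames(as.numeric(par), box$name),
      value = as.numeric(value),
      grid_par = setNames(as.numeric(grid_par), box$name),
      grid_value = as.numeric(grid_value),
      maximize = maximize,
      box = box,
      objective = objective,
      trace = list(n_grid = n_grid, n_points = nrow(grid),
                   polish = polish_info)
    ),
    class = "optimization_result"
  )
}

default_grid_resolution <- function(k) {
  if (k <= 3) 41L else if (k <= 5) 11L else 7L
}

# Indices of the n best distinct grid cells (signed values, descending),
# deterministic.
polish_starts <- function(grid, svals, n_starts) {
  ord <- order(-svals, do.call(order, as.data.frame(grid)))
  keep <- ord[is.finite(svals[ord])]
  utils::head(keep, n_starts)
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result> %s over %d factor(s)\n",
              if (x$maximize) "maximum" else "minimum", length(x$par)))
  cat("coded optimum:\n")
  print(round(x$par, 4))
  if (!is.null(x$decoded)) {
    cat("decoded optimum:\n")
    print(x$decoded, n = Inf)
  }
  cat(sprintf("objective value: %.6g (grid: %.6g)\n", x$value, x$grid_value))
  if (!is.null(x$breakdown)) {
    cat("component breakdown:\n")
    print(x$breakdown, n = Inf)
  }
  invisible(x)
}

#' Tidiers for optimization results
#'
#' `tidy()` returns one row per optimized factor (coded and, when
#' available, decoded values); `glance()` returns a one-row summary.
#'
#' @param x An `optimization_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.optimization_result <- function(x, ...) {
  out <- tibble(name = names(x$par), coded = as.numeric(x$par))
  if (!is.null(x$decoded)) {
    out <- dplyr::left_join(out, x$decoded, by = "name")
  }
  out
}

#' @rdname tidy.optimization_result
#' @export
glance.optimization_result <- function(x, ...) {
  tibble(
    objective = x$value,
    grid_objective = x$grid_value,
    n_factors = length(x$par),
    n_grid = x$trace$n_grid,
    maximize = x$maximize
  )
}

#' Desirability profile plot around an optimum
#'
#' Sweeps each factor across the optimization box while holding the others
#' at the optimum, tracing the objective (composite desirability) along
#' each axis -- the one-factor-at-a-time view practitioners use to judge
#' how sharply the optimum is determined.
#'
#' @param object An `optimization_result`.
#' @param n Points per axis sweep.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.optimization_result <- function(object, n = 101, ...) {
  sweeps <- purrr::map_dfr(seq_along(object$par), function(i) {
    xs <- seq(object$box$lower[i], object$box$upper[i], length.out = n)
    pts <- matrix(rep(object$par, each = n), nrow = n,
                  dimnames = list(NULL, names(object$par)))
    pts[, i] <- xs
    tibble(factor = names(object$par)[i], coded = xs,
           objective = object$objective(pts))
  })
  opt <- tibble(factor = names(object$par), coded = as.numeric(object$par))
  ggplot2::ggplot(sweeps, ggplot2::aes(x = .data$coded, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = opt,
                        ggplot2::aes(xintercept = .data$coded),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~factor, scales = "free_x") +
    ggplot2::labs(x = "coded factor value",
                  y = if (object$maximize) "composite desirability"
                      else "objective")
}
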
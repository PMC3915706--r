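#' Construct a response surface from known coefficients
#'
#' A response surface is a polynomial in the coded factors: a term set plus
#' an aligned coefficient vector, tagged with the role it plays in the
#' study (per-timepoint `mean`, `variance`, `cv`, `covariance`, or a
#' `scalar` release summary such as t50 or f2).
#'
#' @param coefficients Named numeric vector; names are term labels.
#' @param role One of `"mean"`, `"variance"`, `"cv"`, `"covariance"`,
#'   `"scalar"`.
#' @param label Response label the surface belongs to (e.g. `"y1"`).
#' @param pair For covariance surfaces, the two response labels.
#' @return An object of class `response_surface`.
#' @examples
#' s <- response_surface(c("1" = 39.929, x1 = 2.365), "mean", "y1")
#' evaluate_surface(s, c(x1 = 1))
#' @export
response_surface <- function(coefficients, role = "mean", label = NA_character_,
                             pair = NULL) {
  if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
    abort("coefficients must be named by model term",
          class = "releaseopt_term_error")
  }
  if (any(!is.finite(coefficients))) {
    abort("surface coefficients must be finite",
          class = "releaseopt_invalid_value")
  }
  role <- match.arg(role, c("mean", "variance", "cv", "covariance", "scalar"))
  structure(
    list(terms = names(coefficients), coefficients = unname(coefficients),
         role = role, label = label, pair = pair,
         fit = NULL),
    class = "response_surface"
  )
}

#' Fit a response surface by ordinary least squares
#'
#' Solves the normal equations for the polynomial model
#' `y = X(terms) beta + e` over the run settings, the step that turns the
#' per-run summary statistics into surfaces over the coded factor space.
#' The fit is a plain projection: no shrinkage and no constraint that
#' fitted variances stay nonnegative away from the data.
#'
#' @param settings Coded factor settings (matrix/data frame, rows = runs).
#' @param y Numeric response vector, one value per run.
#' @param terms Term set; defaults to the full second-order set in the
#'   setting columns.
#' @inheritParams response_surface
#' @return A `response_surface` whose `fit` element records residuals,
#'   fitted values and degrees of freedom.
#' @examples
#' x <- cbind(x1 = c(-1, 0, 1, 2))
#' fit_surface(x, 1 + 2 * x[, 1]^2, terms = c("1", "x1", "x1^2"))
#' @export
fit_surface <- function(settings, y, terms = NULL, role = "mean",
                        label = NA_character_, pair = NULL) {
  settings <- as_setting_matrix(settings)
  terms <- terms %||% model_terms(colnames(settings))
  X <- build_model_matrix(settings, terms)
  if (nrow(X) < ncol(X)) {
    abort(sprintf("need at least as many runs (%d) as model terms (%d)",
                  nrow(X), ncol(X)),
          class = "releaseopt_singular_design")
  }
  if (length(y) != nrow(X)) {
    abort("response vector length must equal the number of runs",
          class = "releaseopt_invalid_value")
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear term(s): ",
                 paste(dropped, collapse = ", ")),
          class = "releaseopt_singular_design")
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  out <- response_surface(setNames(beta, terms), role = role, label = label,
                          pair = pair)
  out$fit <- list(
    fitted = fitted, residuals = y - fitted, y = y,
    n = nrow(X), df_residual = nrow(X) - ncol(X)
  )
  out
}

#' Evaluate a response surface at coded points
#'
#' @param surface A `response_surface`.
#' @param points A named coded point (numeric vector) or a matrix/data
#'   frame of points with factor columns.
#' @return Numeric vector of surface values, one per point.
#' @export
evaluate_surface <- function(surface, points) {
  stopifnot(inherits(surface, "response_surface"))
  X <- build_model_matrix(as_setting_matrix(points), surface$terms)
  unname(drop(X %*% surface$coefficients))
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf("<response_surface> role=%s label=%s\n", x$role, x$label))
  print(setNames(x$coefficients, x$terms))
  invisible(x)
}

#' @rdname response_surface
#' @param x A `response_surface`.
#' @param ... Unused.
#' @export
tidy.response_surface <- function(x, ...) {
  tibble(term = x$terms, estimate = x$coefficients,
         role = x$role, label = x$label)
}

#' @rdname response_surface
#' @export
glance.response_surface <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(r.squared = NA_real_, sigma = NA_real_,
                  df.residual = NA_integer_, nobs = NA_integer_))
  }
  rss <- sum(x$fit$residuals^2)
  tss <- sum((x$fit$y - mean(x$fit$y))^2)
  tibble(
    r.squared = if (tss > 0) 1 - rss / tss else NA_real_,
    sigma = if (x$fit$df_residual > 0) sqrt(rss / x$fit$df_residual)
            else NA_real_,
    df.residual = as.integer(x$fit$df_residual),
    nobs = as.integer(x$fit$n)
  )
}

#' Stepwise term screening for a response surface
#'
#' Bidirectional stepwise selection on partial F-test p-values, with the
#' intercept always retained. With `scope = "factor"` the selection units
#' are whole factors -- a factor enters or leaves with all terms built from
#' the currently included factors (the screening used when many candidate
#' factors exist); with `scope = "term"` individual polynomial terms move.
#' Ties are broken by the smaller p-value, then canonical term order, so
#' the procedure is deterministic.
#'
#' @inheritParams fit_surface
#' @param p_enter,p_remove Entry/removal p-value thresholds (default 0.05).
#' @param scope `"term"` or `"factor"`.
#' @param force_in Term labels (or factor names under `scope = "factor"`)
#'   always kept in the model.
#' @return Character vector of selected term labels (canonical order), with
#'   attribute `"history"` recording each step.
#' @export
stepwise_select <- function(settings, y, terms = NULL, p_enter = 0.05,
                            p_remove = 0.05, scope = c("term", "factor"),
                            force_in = NULL) {
  scope <- match.arg(scope)
  settings <- as_setting_matrix(settings)
  terms <- terms %||% model_terms(colnames(settings))
  if (!"1" %in% terms) terms <- c("1", terms)

  units <- if (scope == "factor") colnames(settings) else setdiff(terms, "1")
  force_in <- intersect(force_in %||% character(0), units)

  terms_for <- function(active_units) {
    if (scope == "term") return(intersect(terms, c("1", active_units)))
    keep <- vapply(terms, function(tm) {
      v <- parse_term(tm)$vars
      length(v) == 0 || all(v %in% active_units)
    }, logical(1))
    terms[keep]
  }
  rss_of <- function(tms) {
    X <- build_model_matrix(settings, tms)
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) return(NULL)
    sum(qr.resid(qrx, y)^2)
  }
  ftest_p <- function(rss0, rss1, df_extra, df_res1) {
    if (is.null(rss0) || is.null(rss1) || df_res1 <= 0) return(NA_real_)
    if (rss1 <= 0) return(0)
    f <- ((rss0 - rss1) / df_extra) / (rss1 / df_res1)
    pf(max(f, 0), df_extra, df_res1, lower.tail = FALSE)
  }
  n <- length(y)

  active <- force_in
  history <- list()
  for (step_i in seq_len(50)) {
    moved <- FALSE
    # backward: drop the least significant removable unit
    removable <- setdiff(active, force_in)
    if (length(removable) > 0) {
      cur_terms <- terms_for(active)
      rss_cur <- rss_of(cur_terms)
      pvals <- vapply(removable, function(u) {
        reduced <- terms_for(setdiff(active, u))
        df_extra <- length(cur_terms) - length(reduced)
        if (df_extra == 0) return(1)
        ftest_p(rss_of(reduced), rss_cur, df_extra, n - length(cur_terms))
      }, numeric(1))
      worst <- which(pvals > p_remove | is.na(pvals))
      if (length(worst) > 0) {
        pick <- worst[order(-pvals[worst], match(removable[worst], units))][1]
        active <- setdiff(active, removable[pick])
        history[[length(history) + 1]] <-
          tibble(step = step_i, action = "remove", unit = removable[pick],
                 p = pvals[pick])
        moved <- TRUE
      }
    }
    if (!moved) {
      # forward: add the most significant candidate below the threshold
      candidates <- setdiff(units, active)
      if (length(candidates) > 0) {
        cur_terms <- terms_for(active)
        rss_cur <- rss_of(cur_terms)
        pvals <- vapply(candidates, function(u) {
          bigger <- terms_for(c(active, u))
          df_extra <- length(bigger) - length(cur_terms)
          if (df_extra == 0) return(NA_real_)
          if (length(bigger) >= n) return(NA_real_)
          ftest_p(rss_cur, rss_of(bigger), df_extra, n - length(bigger))
        }, numeric(1))
        ok <- which(!is.na(pvals) & pvals < p_enter)
        if (length(ok) > 0) {
          pick <- ok[order(pvals[ok], match(candidates[ok], units))][1]
          active <- c(active, candidates[pick])
          history[[length(history) + 1]] <-
            tibble(step = step_i, action = "add", unit = candidates[pick],
                   p = pvals[pick])
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  out <- terms_for(active)
  attr(out, "history") <- dplyr::bind_rows(history)
  out
}

#' Fit surfaces for every summary statistic of a study
#'
#' Runs [fit_surface()] over the per-run summary of a replicated design:
#' one mean, variance and cv surface per time point, and one covariance
#' surface per time-point pair.
#'
#' @param summary A `run_summary` from [summarize_runs()].
#' @param terms Term set used for every surface; defaults to the full
#'   second-order set in the summary's factors.
#' @param covariances Fit covariance surfaces too?
#' @return A named list of `response_surface` objects of class
#'   `surface_set`; names are `mean_<tp>`, `var_<tp>`, `cv_<tp>`,
#'   `cov_<tpi>_<tpj>`.
#' @export
fit_surfaces <- function(summary, terms = NULL, covariances = TRUE) {
  stopifnot(inherits(summary, "run_summary"))
  settings <- as.matrix(summary$settings[summary$factors])
  terms <- terms %||% model_terms(summary$factors)
  out <- list()
  for (tp in summary$timepoints) {
    block <- summary$stats[summary$stats$timepoint == tp, ]
    block <- block[match(summary$settings$run, block$run), ]
    out[[paste0("mean_", tp)]] <-
      fit_surface(settings, block$mean, terms, role = "mean", label = tp)
    out[[paste0("var_", tp)]] <-
      fit_surface(settings, block$var, terms, role = "variance", label = tp)
    out[[paste0("cv_", tp)]] <-
      fit_surface(settings, block$cv, terms, role = "cv", label = tp)
  }
  if (covariances && nrow(summary$covariances) > 0) {
    pairs <- dplyr::distinct(summary$covariances[c("timepoint_i",
                                                   "timepoint_j")])
    for (i in seq_len(nrow(pairs))) {
      pi <- pairs$timepoint_i[i]; pj <- pairs$timepoint_j[i]
      block <- summary$covariances[summary$covariances$timepoint_i == pi &
                                     summary$covariances$timepoint_j == pj, ]
      block <- block[match(summary$settings$run, block$run), ]
      out[[paste0("cov_", pi, "_", pj)]] <-
        fit_surface(settings, block$cov, terms, role = "covariance",
                    label = paste0(pi, "_", pj), pair = c(pi, pj))
    }
  }
  structure(out, class = c("surface_set", "list"))
}

#' @export
print.surface_set <- function(x, ...) {
  cat(sprintf("<surface_set> %d surface(s): %s\n", length(x),
              paste(head(names(x), 8), collapse = ", ")))
  invisible(x)
}

#' @rdname fit_surfaces
#' @param x A `surface_set`.
#' @param ... Unused.
#' @export
tidy.surface_set <- function(x, ...) {
  purrr::map_dfr(x, tidy, .id = "surface")
}
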
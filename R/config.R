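#' Target release-profile specifications
#'
#' One row per response: a time point of the target dissolution profile, or
#' a scalar release summary (t50, mean dissolution time, f2) without a time.
#' Each carries its quality-characteristic class and specification limits:
#'
#' * `NTB` (nominal-the-best): `lsl < target < usl`;
#' * `LTB` (larger-the-better): `lsl` = lowest acceptable, `usl` = ideal;
#' * `STB` (smaller-the-better): `lsl` = ideal, `usl` = highest acceptable.
#'
#' The four weight columns set the relative weight of this response's mean,
#' variance, coefficient-of-variation and covariance components in the
#' composite desirability.
#'
#' @param label Character vector of response identifiers (e.g. `"y1"`).
#' @param time Numeric vector of sampling times in hours; `NA` for scalar
#'   summaries.
#' @param kind One of `"NTB"`, `"LTB"`, `"STB"` per response.
#' @param lsl,target,usl Specification limits in response units (percent
#'   released for profile points). `target` applies to NTB only.
#' @param weight_mean,weight_var,weight_cv,weight_cov Nonnegative component
#'   weights, default 1 for the mean and 1 for the others.
#' @return A validated tibble of response specifications.
#' @examples
#' response_table(
#'   label = c("y1", "y2"), time = c(1, 6), kind = "NTB",
#'   lsl = c(20, 50), target = c(30, 60), usl = c(40, 70)
#' )
#' @export
response_table <- function(label, time = NA_real_, kind = "NTB",
                           lsl = NA_real_, target = NA_real_, usl = NA_real_,
                           weight_mean = 1, weight_var = 1,
                           weight_cv = 1, weight_cov = 1) {
  out <- tibble(
    label = as.character(label),
    time = as.numeric(time),
    kind = as.character(kind),
    lsl = as.numeric(lsl),
    target = as.numeric(target),
    usl = as.numeric(usl),
    weight_mean = as.numeric(weight_mean),
    weight_var = as.numeric(weight_var),
    weight_cv = as.numeric(weight_cv),
    weight_cov = as.numeric(weight_cov)
  )
  validate_response_table(out)
}

validate_response_table <- function(responses) {
  required <- c("label", "kind", "lsl", "target", "usl")
  missing <- setdiff(required, names(responses))
  if (length(missing) > 0) {
    abort(paste0("response table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "releaseopt_schema_error")
  }
  if (nrow(responses) == 0) {
    abort("response table must contain at least one response",
          class = "releaseopt_schema_error")
  }
  if (anyDuplicated(responses$label)) {
    abort("response labels must be unique", class = "releaseopt_schema_error")
  }
  bad_kind <- setdiff(unique(responses$kind), c("NTB", "LTB", "STB"))
  if (length(bad_kind) > 0) {
    abort(paste0("unknown response kind: ", paste(bad_kind, collapse = ", ")),
          class = "releaseopt_schema_error")
  }
  for (i in seq_len(nrow(responses))) {
    r <- responses[i, ]
    ok <- switch(r$kind,
      NTB = isTRUE(r$lsl < r$target && r$target < r$usl),
      LTB = ,
      STB = isTRUE(r$lsl < r$usl)
    )
    if (!ok) {
      abort(sprintf(
        "response '%s' (%s): specification limits must be strictly ordered",
        r$label, r$kind), class = "releaseopt_schema_error")
    }
  }
  wcols <- grep("^weight_", names(responses), value = TRUE)
  if (length(wcols) > 0) {
    w <- as.matrix(responses[wcols])
    if (any(w < 0) || any(!is.finite(w))) {
      abort("response weights must be finite and nonnegative",
            class = "releaseopt_schema_error")
    }
    if (all(rowSums(w) == 0)) {
      abort("at least one response weight must be positive",
            class = "releaseopt_schema_error")
    }
  }
  as_tibble(responses)
}

#' Assemble a dissolution study configuration
#'
#' Bundles the controllable factors, the target-profile response
#' specifications and the coded optimization box into one object, the
#' central input to the fitting and optimization pipeline.
#'
#' @param factors A factor table (see [factor_table()]).
#' @param responses A response table (see [response_table()]).
#' @param box Optional tibble/data frame with columns `name`, `lower`,
#'   `upper` giving the coded optimization interval per factor. Defaults to
#'   the range of each factor's coded design levels (published optima can
#'   sit on design-level boundaries well outside \[-1, 1\]).
#' @return An object of class `study_config`.
#' @export
study_config <- function(factors, responses, box = NULL) {
  factors <- validate_factor_table(factors)
  responses <- validate_response_table(responses)
  lv <- coded_levels(factors)
  if (is.null(box)) {
    box <- tibble(
      name = factors$name,
      lower = unname(vapply(lv, min, numeric(1))),
      upper = unname(vapply(lv, max, numeric(1)))
    )
  }
  box <- as_tibble(box)
  if (!all(c("name", "lower", "upper") %in% names(box))) {
    abort("box needs columns name, lower, upper",
          class = "releaseopt_schema_error")
  }
  box <- box[match(factors$name, box$name), ]
  if (any(is.na(box$name))) {
    abort("box must cover every factor", class = "releaseopt_schema_error")
  }
  if (any(box$lower >= box$upper)) {
    abort("box intervals must be nonempty", class = "releaseopt_schema_error")
  }
  for (i in seq_along(lv)) {
    if (min(lv[[i]]) < box$lower[i] - 1e-9 || max(lv[[i]]) > box$upper[i] + 1e-9) {
      abort(sprintf("box for factor '%s' must contain its coded design levels",
                    factors$name[i]),
            class = "releaseopt_schema_error")
    }
  }
  structure(
    list(factors = factors, responses = responses, box = box),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf("<study_config> %d factor(s), %d response(s)\n",
              nrow(x$factors), nrow(x$responses)))
  cat("Factors:\n")
  print(x$factors, n = Inf)
  cat("Responses:\n")
  print(x$responses, n = Inf)
  invisible(x)
}

#' Read and write study configurations
#'
#' Study configurations serialize to a YAML document with keys `factors`
#' (list of `{name, label, unit, levels, center, scale}`), `responses`
#' (list of `{label, time, kind, lsl, target, usl, weights}`) and `box`
#' (list of `{name, lower, upper}`). The round trip is lossless.
#'
#' @param path File path of the YAML document.
#' @param config A `study_config` object.
#' @return `load_study_config()` returns a `study_config`;
#'   `save_study_config()` returns `path` invisibly.
#' @export
load_study_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("no such config file: ", path),
          class = "releaseopt_schema_error")
  }
  study_config_from_list(yaml::read_yaml(path))
}

#' @rdname load_study_config
#' @export
save_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  yaml::write_yaml(study_config_to_list(config), path, precision = 15)
  invisible(path)
}

study_config_to_list <- function(config) {
  list(
    factors = purrr::pmap(config$factors, function(name, label, unit, center,
                                                   scale, levels) {
      list(name = name, label = label, unit = unit,
           levels = as.numeric(levels), center = center, scale = scale)
    }),
    responses = purrr::pmap(config$responses, function(label, time, kind, lsl,
                                                       target, usl, ...) {
      w <- list(...)
      list(label = label, time = null_if_na(time), kind = kind,
           lsl = null_if_na(lsl), target = null_if_na(target),
           usl = null_if_na(usl),
           weights = list(mean = w$weight_mean, var = w$weight_var,
                          cv = w$weight_cv, cov = w$weight_cov))
    }),
    box = purrr::pmap(config$box, function(name, lower, upper) {
      list(name = name, lower = lower, upper = upper)
    })
  )
}

study_config_from_list <- function(x) {
  for (key in c("factors", "responses")) {
    if (is.null(x[[key]]) || length(x[[key]]) == 0) {
      abort(paste0("config is missing a non-empty '", key, "' section"),
            class = "releaseopt_schema_error")
    }
  }
  need <- function(item, field, where) {
    if (is.null(item[[field]])) {
      abort(sprintf("config %s entry is missing field '%s'", where, field),
            class = "releaseopt_schema_error")
    }
    item[[field]]
  }
  factors <- purrr::map_dfr(x$factors, function(f) {
    tibble(
      name = as.character(need(f, "name", "factors")),
      label = as.character(f$label %||% f$name),
      unit = as.character(f$unit %||% NA_character_),
      center = as.numeric(need(f, "center", "factors")),
      scale = as.numeric(need(f, "scale", "factors")),
      levels = list(as.numeric(need(f, "levels", "factors")))
    )
  })
  responses <- purrr::map_dfr(x$responses, function(r) {
    w <- r$weights %||% list()
    tibble(
      label = as.character(need(r, "label", "responses")),
      time = as.numeric(r$time %||% NA_real_),
      kind = as.character(need(r, "kind", "responses")),
      lsl = as.numeric(r$lsl %||% NA_real_),
      target = as.numeric(r$target %||% NA_real_),
      usl = as.numeric(r$usl %||% NA_real_),
      weight_mean = as.numeric(w$mean %||% 1),
      weight_var = as.numeric(w$var %||% 1),
      weight_cv = as.numeric(w$cv %||% 1),
      weight_cov = as.numeric(w$cov %||% 1)
    )
  })
  box <- NULL
  if (!is.null(x$box)) {
    box <- purrr::map_dfr(x$box, function(b) {
      tibble(name = as.character(need(b, "name", "box")),
             lower = as.numeric(need(b, "lower", "box")),
             upper = as.numeric(need(b, "upper", "box")))
    })
  }
  study_config(factors, responses, box)
}

null_if_na <- function(x) if (length(x) == 1 && is.na(x)) NULL else x
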
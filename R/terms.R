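#' Second-order model term sets
#'
#' Response surfaces are polynomials in the coded factors. A term set is an
#' ordered character vector of term labels drawn from the controlled
#' vocabulary `"1"` (intercept), `"x"` (linear), `"x^2"` (quadratic) and
#' `"xa:xb"` (pairwise interaction). `model_terms()` builds the canonical
#' full set for `k` factors: intercept, linear terms in factor order,
#' quadratic terms, then interactions `xi:xj` with `i < j`; its length is
#' `1 + 2k + k(k-1)/2`.
#'
#' @param factor_names Character vector of factor identifiers.
#' @param order Polynomial order, 1 (linear) or 2 (full second-order).
#' @param interactions Include pairwise interactions (order 2 only)?
#' @return Character vector of term labels in canonical order.
#' @examples
#' model_terms(c("x1", "x2"))
#' @export
model_terms <- function(factor_names, order = 2, interactions = TRUE) {
  stopifnot(length(factor_names) >= 1, order %in% c(1, 2))
  out <- c("1", factor_names)
  if (order == 2) {
    out <- c(out, paste0(factor_names, "^2"))
    if (interactions && length(factor_names) >= 2) {
      idx <- utils::combn(seq_along(factor_names), 2)
      out <- c(out, paste0(factor_names[idx[1, ]], ":", factor_names[idx[2, ]]))
    }
  }
  out
}

# Parse a term label into its factors and powers. "1" -> empty.
parse_term <- function(term) {
  if (term == "1") return(list(vars = character(0), powers = integer(0)))
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  vars <- character(0)
  powers <- integer(0)
  for (p in parts) {
    if (grepl("\\^", p)) {
      bits <- strsplit(p, "^", fixed = TRUE)[[1]]
      vars <- c(vars, bits[1])
      powers <- c(powers, as.integer(bits[2]))
    } else {
      vars <- c(vars, p)
      powers <- c(powers, 1L)
    }
  }
  list(vars = vars, powers = powers)
}

#' Build the design matrix for a term set
#'
#' Expands coded factor settings into the model matrix of a polynomial
#' term set: one row per setting, one column per term, the intercept column
#' of ones first.
#'
#' @param settings A numeric matrix or data frame of coded factor settings
#'   (rows = runs, named columns = factors), or a single named numeric
#'   vector.
#' @param terms Character vector of term labels (see [model_terms()]).
#' @return Numeric matrix with `length(terms)` columns named by term.
#' @examples
#' build_model_matrix(cbind(x1 = c(1, 2)), c("1", "x1", "x1^2"))
#' @export
build_model_matrix <- function(settings, terms) {
  settings <- as_setting_matrix(settings)
  if (anyDuplicated(terms)) {
    abort("duplicate model terms", class = "releaseopt_term_error")
  }
  cols <- lapply(terms, function(tm) {
    p <- parse_term(tm)
    if (length(p$vars) == 0) return(rep(1, nrow(settings)))
    missing <- setdiff(p$vars, colnames(settings))
    if (length(missing) > 0) {
      abort(paste0("term '", tm, "' references unknown factor(s): ",
                   paste(missing, collapse = ", ")),
            class = "releaseopt_term_error")
    }
    out <- rep(1, nrow(settings))
    for (i in seq_along(p$vars)) {
      out <- out * settings[, p$vars[i]]^p$powers[i]
    }
    out
  })
  m <- do.call(cbind, cols)
  colnames(m) <- terms
  m
}

as_setting_matrix <- function(settings, factor_names = NULL) {
  if (is.numeric(settings) && is.null(dim(settings))) {
    nm <- names(settings) %||% factor_names
    if (is.null(nm)) {
      abort("a single coded point must be a named numeric vector",
            class = "releaseopt_term_error")
    }
    settings <- matrix(settings, nrow = 1, dimnames = list(NULL, nm))
  }
  if (is.data.frame(settings)) settings <- as.matrix(settings)
  if (is.null(colnames(settings)) && !is.null(factor_names)) {
    colnames(settings) <- factor_names
  }
  storage.mode(settings) <- "double"
  settings
}
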
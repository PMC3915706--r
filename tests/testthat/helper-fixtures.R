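# Shared builders for small synthetic studies used across tests.

# A one-factor factor table with midpoint coding.
toy_factor <- function(name = "x1", center = 0, scale = 1,
                       levels = c(-1, 0, 1) * scale + center) {
  factor_table(name, center = center, scale = scale, levels = list(levels))
}

# Full factorial coded design for k factors at levels -1, 0, 1.
factorial_design <- function(k, levels = c(-1, 0, 1)) {
  as.matrix(do.call(expand.grid,
                    setNames(rep(list(levels), k), paste0("x", seq_len(k)))))
}

# A quadratic truth surface over k factors with fixed coefficients.
truth_surface <- function(k, intercept = 30, lin = NULL, quad = NULL,
                          label = "y1", role = "mean") {
  terms <- model_terms(paste0("x", seq_len(k)))
  beta <- numeric(length(terms))
  names(beta) <- terms
  beta["1"] <- intercept
  lin <- lin %||% rep(2, k)
  quad <- quad %||% rep(-1, k)
  beta[paste0("x", seq_len(k))] <- lin
  beta[paste0("x", seq_len(k), "^2")] <- quad
  response_surface(beta, role = role, label = label)
}

# Long design table with deterministic values from a surface plus optional
# per-replicate offsets (offsets recycle over replicates).
deterministic_table <- function(surface, design, m = 3, offsets = 0) {
  mu <- evaluate_surface(surface, design)
  purrr::map_dfr(seq_len(nrow(design)), function(r) {
    vals <- mu[r] + rep_len(offsets, m)
    dplyr::bind_cols(
      tibble::tibble(run = r),
      tibble::as_tibble(as.data.frame(design[rep(r, m), , drop = FALSE])),
      tibble::tibble(timepoint = surface$label, replicate = seq_len(m),
                     value = vals)
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
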
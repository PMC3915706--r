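test_that("model matrices expand settings in canonical term order", {
  expect_equal(
    unname(build_model_matrix(cbind(x1 = 2), c("1", "x1", "x1^2"))),
    matrix(c(1, 2, 4), nrow = 1))
  m <- build_model_matrix(cbind(x1 = 1, x2 = -1), model_terms(c("x1", "x2")))
  expect_equal(colnames(m), c("1", "x1", "x2", "x1^2", "x2^2", "x1:x2"))
  expect_equal(unname(m), matrix(c(1, 1, -1, 1, 1, -1), nrow = 1))
  many <- build_model_matrix(factorial_design(2), model_terms(c("x1", "x2")))
  expect_equal(nrow(many), 9)
  expect_error(build_model_matrix(cbind(x1 = 1), c("1", "x1", "x1")),
               class = "releaseopt_term_error")
  expect_error(build_model_matrix(cbind(x1 = 1), c("1", "x9")),
               class = "releaseopt_term_error")
})

test_that("noiseless quadratic data reproduces its generating coefficients", {
  truth <- truth_surface(2, intercept = 12, lin = c(3, -1.5),
                         quad = c(0.8, 2))
  design <- factorial_design(2)
  y <- evaluate_surface(truth, design)
  fit <- fit_surface(design, y)
  expect_equal(fit$coefficients, truth$coefficients, tolerance = 1e-8)
  # constant response: intercept only
  cfit <- fit_surface(design, rep(4.2, nrow(design)))
  expect_equal(cfit$coefficients[1], 4.2, tolerance = 1e-10)
  expect_equal(cfit$coefficients[-1], rep(0, 5), tolerance = 1e-10)
})

test_that("fit_surface agrees with a brute-force normal-equations oracle", {
  set.seed(21)
  for (i in 1:50) {
    k <- sample(1:3, 1)
    n <- sample((2 * k + 2 + k * (k - 1) / 2):12, 1)
    design <- matrix(runif(n * k, -1.5, 1.5), ncol = k,
                     dimnames = list(NULL, paste0("x", seq_len(k))))
    y <- rnorm(n, sd = 3)
    terms <- model_terms(colnames(design))
    X <- build_model_matrix(design, terms)
    beta_oracle <- solve(t(X) %*% X, t(X) %*% y)  # (x'x)^-1 x'y
    fit <- fit_surface(design, y, terms)
    expect_equal(fit$coefficients, drop(beta_oracle), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("refitting the fitted values is idempotent", {
  set.seed(5)
  design <- factorial_design(2)
  y <- rnorm(nrow(design), 50, 5)
  fit <- fit_surface(design, y)
  refit <- fit_surface(design, fit$fit$fitted)
  expect_equal(refit$coefficients, fit$coefficients, tolerance = 1e-10)
  # residuals orthogonal to the column space
  X <- build_model_matrix(design, fit$terms)
  expect_equal(drop(t(X) %*% fit$fit$residuals), rep(0, ncol(X)),
               tolerance = 1e-8, ignore_attr = TRUE)
  td <- tidy(fit)
  expect_equal(td$term, fit$terms)
  expect_equal(td$estimate, fit$coefficients)
  g <- glance(fit)
  expect_equal(g$nobs, nrow(design))
  expect_true(g$r.squared >= 0 && g$r.squared <= 1)
})

test_that("rank-deficient designs raise an error naming collinear terms", {
  design <- cbind(x1 = c(-1, 0, 1, 2), x2 = c(-2, 0, 2, 4))  # x2 = 2 x1
  expect_error(fit_surface(design, rnorm(4), c("1", "x1", "x2")),
               "x2", class = "releaseopt_singular_design")
  expect_error(fit_surface(cbind(x1 = c(0, 1)), rnorm(2),
                           c("1", "x1", "x1^2")),
               class = "releaseopt_singular_design")
})

test_that("published surfaces evaluate exactly at reference points", {
  fx1 <- load_example("diclofenac")
  origin3 <- c(x1 = 0, x2 = 0, x3 = 0)
  expect_equal(evaluate_surface(fx1$surfaces$mean_y1, origin3), 39.929)
  fx6 <- load_example("metoprolol")
  expect_equal(evaluate_surface(fx6$surfaces$mean_t50, c(x1 = 0, x2 = 0)),
               6.222)
  # at the all-ones point every term equals 1: value = sum of coefficients
  ones <- setNames(rep(1, 3), c("x1", "x2", "x3"))
  for (s in fx1$surfaces[c("mean_y2", "var_y3", "cov_y1_y2")]) {
    expect_equal(evaluate_surface(s, ones), sum(s$coefficients))
  }
})

test_that("fixture mean surfaces stay at release-percentage magnitudes", {
  for (name in example_names()) {
    fx <- load_example(name)
    pts <- design_points(fx$config$factors)
    for (nm in grep("^mean_", names(fx$surfaces), value = TRUE)) {
      v <- evaluate_surface(fx$surfaces[[nm]], pts)
      expect_true(all(is.finite(v)), label = paste(name, nm))
    }
  }
})

test_that("stepwise keeps real signal factors and drops pure noise factors", {
  set.seed(31)
  n <- 60
  design <- matrix(runif(n * 3, -1, 1), ncol = 3,
                   dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- 5 + 4 * design[, "x1"] - 3 * design[, "x1"]^2 + rnorm(n, sd = 0.3)
  sel <- stepwise_select(design, y, scope = "factor")
  expect_true(all(c("x1", "x1^2") %in% sel))
  expect_false("x2" %in% sel)
  expect_false("x3" %in% sel)
  sel_t <- stepwise_select(design, y, scope = "term")
  expect_true(all(c("x1", "x1^2") %in% sel_t))
})

test_that("stepwise on pure noise usually retains only the intercept", {
  set.seed(41)
  n_sims <- 40
  only_intercept <- 0
  for (i in seq_len(n_sims)) {
    design <- matrix(runif(20 * 3, -1, 1), ncol = 3,
                     dimnames = list(NULL, c("x1", "x2", "x3")))
    y <- rnorm(20)
    sel <- stepwise_select(design, y, scope = "factor")
    if (identical(as.character(sel), "1")) only_intercept <- only_intercept + 1
  }
  # familywise false-entry over 3 candidate factors at alpha = 0.05 is
  # roughly 1 - 0.95^3 ~ 14%, so the large majority of replicates keep
  # nothing but the intercept
  expect_gte(only_intercept / n_sims, 0.75)
})

test_that("forcing every unit in reproduces the full fit", {
  set.seed(8)
  design <- factorial_design(2)
  y <- rnorm(nrow(design), 40, 6)
  sel <- stepwise_select(design, y, scope = "factor",
                         force_in = c("x1", "x2"))
  expect_setequal(sel, model_terms(c("x1", "x2")))
  full <- fit_surface(design, y)
  forced <- fit_surface(design, y, terms = sel)
  expect_equal(sort(forced$coefficients), sort(full$coefficients),
               tolerance = 1e-10)
})
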
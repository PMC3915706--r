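test_that("replicate statistics match hand arithmetic", {
  expect_equal(run_mean(c(2, 4, 6)), 4)
  expect_equal(run_mean(c(30.1, 29.9, 31.0, 29.0)), 30.0)
  expect_equal(run_mean(rep(7.3, 5)), 7.3)

  expect_equal(run_variance(c(1, 3)), 2)
  expect_equal(run_variance(c(2, 4, 6)), 4)
  expect_equal(run_variance(rep(5, 4)), 0)

  expect_equal(run_cv(c(1, 3)), sqrt(2) / 2)
  expect_equal(run_cv(rep(3, 4)), 0)

  expect_equal(run_covariance(c(1, 3), c(3, 1)), -2)
  a <- c(2.5, 3.1, 2.9)
  expect_equal(run_covariance(a, a), run_variance(a))
  expect_equal(run_covariance(a, rep(4, 3)), 0)
})

test_that("cv is invariant to positive rescaling of the observations", {
  set.seed(3)
  for (i in 1:10) {
    x <- runif(4, 10, 90)
    k <- runif(1, 0.1, 20)
    expect_equal(run_cv(k * x), run_cv(x), tolerance = 1e-12)
  }
})

test_that("degenerate replicate inputs raise typed errors", {
  expect_error(run_mean(numeric(0)),
               class = "releaseopt_insufficient_replicates")
  expect_error(run_variance(5),
               class = "releaseopt_insufficient_replicates")
  expect_error(run_cv(c(-1, 1)), class = "releaseopt_undefined_cv")
  expect_error(run_covariance(c(1, 2), c(1, 2, 3)),
               class = "releaseopt_pairing_error")
})

make_table <- function(n_run = 3, tps = c("y1", "y2"), m = 3, noise = 0,
                       seed = 7) {
  set.seed(seed)
  tidyr::expand_grid(run = seq_len(n_run), timepoint = tps,
                     replicate = seq_len(m)) |>
    dplyr::mutate(
      x1 = (run - 2) / 1,
      value = 30 + 5 * x1 + 10 * (timepoint == "y2") +
        noise * rnorm(dplyr::n())
    )
}

test_that("summarize_runs has the design's shape and zero-noise variances", {
  tbl <- make_table()
  s <- summarize_runs(tbl)
  expect_s3_class(s, "run_summary")
  expect_equal(nrow(s$stats), 3 * 2)
  expect_equal(nrow(s$covariances), 3 * 1)
  expect_equal(s$stats$var, rep(0, 6))
  expect_equal(s$stats$cv, rep(0, 6))
  expect_equal(sort(unique(s$stats$m)), 3)
  long <- tidy(s)
  expect_equal(nrow(long), 6 * 3 + 3)
})

test_that("per-run moment matrices are symmetric positive semi-definite", {
  tbl <- make_table(n_run = 4, tps = c("y1", "y2", "y3"), m = 5, noise = 2)
  s <- summarize_runs(tbl)
  for (r in s$settings$run) {
    v <- s$stats[s$stats$run == r, ]
    cv <- s$covariances[s$covariances$run == r, ]
    tps <- v$timepoint
    m <- diag(v$var)
    dimnames(m) <- list(tps, tps)
    for (i in seq_len(nrow(cv))) {
      m[cv$timepoint_i[i], cv$timepoint_j[i]] <- cv$cov[i]
      m[cv$timepoint_j[i], cv$timepoint_i[i]] <- cv$cov[i]
    }
    expect_true(isSymmetric(m))
    expect_true(min(eigen(m, symmetric = TRUE,
                          only.values = TRUE)$values) > -1e-10)
  }
})

test_that("summary is invariant to paired reordering of replicates", {
  tbl <- make_table(noise = 3)
  s1 <- summarize_runs(tbl)
  # reverse replicate ids consistently across all time points of run 2
  tbl2 <- dplyr::mutate(tbl, replicate = ifelse(run == 2, 4 - replicate,
                                                replicate))
  tbl2 <- dplyr::arrange(tbl2, run, timepoint, replicate)
  s2 <- summarize_runs(tbl2)
  expect_equal(s1$stats, s2$stats)
  expect_equal(s1$covariances, s2$covariances)
})

test_that("covariances estimate the generating covariance at large m", {
  sigma <- matrix(c(4, 1.5, 1.5, 2), 2, 2)
  truth1 <- truth_surface(1, intercept = 40, label = "y1")
  truth2 <- truth_surface(1, intercept = 60, label = "y2")
  spec <- synthetic_spec(list(y1 = truth1, y2 = truth2),
                         cbind(x1 = 0), sigma = sigma, m = 4000, seed = 99)
  s <- summarize_runs(generate_experiment(spec))
  expect_equal(s$stats$var, diag(sigma), tolerance = 0.1)
  expect_equal(s$covariances$cov, 1.5, tolerance = 0.15)
})

test_that("incomplete or inconsistent design tables are rejected", {
  tbl <- make_table()
  expect_error(summarize_runs(tbl[-1, ]), class = "releaseopt_schema_error")
  bad <- tbl
  bad$x1[1] <- 99
  expect_error(summarize_runs(bad), class = "releaseopt_schema_error")
  expect_error(summarize_runs(dplyr::select(tbl, -"value")),
               class = "releaseopt_schema_error")
  one_rep <- dplyr::filter(tbl, replicate == 1)
  expect_error(summarize_runs(one_rep),
               class = "releaseopt_insufficient_replicates")
})

test_that("design tables round trip through CSV", {
  tbl <- make_table(noise = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_table(tbl, path)
  back <- read_design_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl), tolerance = 1e-12)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("run,foo\n1,2", bad)
  expect_error(read_design_table(bad), class = "releaseopt_schema_error")
})
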
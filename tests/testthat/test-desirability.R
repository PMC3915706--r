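test_that("NTB desirability hits its anchor points", {
  # 1-hour profile point: LSL 20, target 30, USL 40
  expect_equal(d_ntb(30, 20, 30, 40), 1)
  expect_equal(d_ntb(20, 20, 30, 40), 0)
  expect_equal(d_ntb(40, 20, 30, 40), 0)
  expect_equal(d_ntb(12, 20, 30, 40), 0)
  expect_equal(d_ntb(55, 20, 30, 40), 0)
  expect_equal(d_ntb(25, 20, 30, 40), 0.5)
  expect_equal(d_ntb(35, 20, 30, 40), 0.5)
  expect_equal(d_ntb(25, 20, 30, 40, r = 2), 0.25)
  expect_equal(d_ntb(35, 20, 30, 40, s = 2), 0.25)
})

test_that("LTB and STB desirabilities ramp between their bounds", {
  expect_equal(d_ltb(120, 50, 100), 1)
  expect_equal(d_ltb(30, 50, 100), 0)
  expect_equal(d_ltb(75, 50, 100), 0.5)
  expect_equal(d_stb(-1, 0, 10), 1)
  expect_equal(d_stb(15, 0, 10), 0)
  expect_equal(d_stb(5, 0, 10), 0.5)
  expect_equal(d_stb(5, 0, 10, r = 3), 0.125)
})

test_that("desirabilities are bounded in [0,1] and monotone as specified", {
  set.seed(17)
  for (i in 1:30) {
    b <- sort(runif(3, -50, 50))
    r <- runif(1, 0.2, 4)
    s <- runif(1, 0.2, 4)
    ys <- seq(b[1] - 10, b[3] + 10, length.out = 201)
    d <- d_ntb(ys, b[1], b[2], b[3], r, s)
    expect_true(all(d >= 0 & d <= 1))
    expect_true(all(diff(d[ys <= b[2]]) >= -1e-12))
    expect_true(all(diff(d[ys >= b[2]]) <= 1e-12))
    dl <- d_ltb(ys, b[1], b[3], r)
    expect_true(all(diff(dl) >= -1e-12) && all(dl >= 0 & dl <= 1))
    ds <- d_stb(ys, b[1], b[3], r)
    expect_true(all(diff(ds) <= 1e-12) && all(ds >= 0 & ds <= 1))
  }
})

test_that("linear NTB matches an independently coded piecewise formula", {
  piecewise <- function(y, lsl, t, usl) {
    ifelse(y <= lsl | y >= usl, 0,
           ifelse(y <= t, (y - lsl) / (t - lsl), (usl - y) / (usl - t)))
  }
  ys <- seq(0, 100, by = 0.25)
  expect_equal(d_ntb(ys, 20, 30, 40), piecewise(ys, 20, 30, 40))
  expect_equal(d_ntb(ys, 65, 72.5, 80), piecewise(ys, 65, 72.5, 80))
})

surfaces_for_composite <- function(values) {
  out <- purrr::imap(values, function(v, nm) {
    response_surface(c("1" = v), role = "mean", label = nm)
  })
  out
}

test_that("composite desirability is a weighted geometric mean", {
  sf <- surfaces_for_composite(list(a = 30, b = 5))
  spec <- composite_spec(
    surface = c("a", "b"), kind = c("NTB", "STB"),
    lsl = c(20, 0), target = c(30, NA), usl = c(40, 10), weight = c(1, 1)
  )
  res <- composite_desirability(c(x1 = 0), sf, spec)
  expect_equal(res$value, sqrt(1 * 0.5))
  expect_equal(res$breakdown$desirability, c(1, 0.5))

  # components {0.25, 1} with equal weights -> sqrt(0.25) = 0.5
  sf2 <- surfaces_for_composite(list(a = 22.5, b = -3))
  res2 <- composite_desirability(c(x1 = 0), sf2, spec)
  expect_equal(res2$breakdown$desirability, c(0.25, 1))
  expect_equal(res2$value, 0.5)
})

test_that("any positively weighted zero component annihilates the composite", {
  sf <- surfaces_for_composite(list(a = 30, b = 50))  # b far above its USL
  spec <- composite_spec(
    surface = c("a", "b"), kind = c("NTB", "STB"),
    lsl = c(20, 0), target = c(30, NA), usl = c(40, 10), weight = c(1, 1)
  )
  expect_equal(composite_desirability(c(x1 = 0), sf, spec)$value, 0)
  # weight 0 turns the dead component off
  spec0 <- spec
  spec0$weight <- c(1, 0)
  expect_equal(composite_desirability(c(x1 = 0), sf, spec0)$value, 1)
})

test_that("the composite is invariant to rescaling all weights", {
  sf <- surfaces_for_composite(list(a = 26, b = 4, c = 60))
  spec <- composite_spec(
    surface = c("a", "b", "c"), kind = c("NTB", "STB", "LTB"),
    lsl = c(20, 0, 50), target = c(30, NA, NA), usl = c(40, 10, 100),
    weight = c(1, 2, 0.5)
  )
  base <- composite_desirability(c(x1 = 0), sf, spec)$value
  for (k in c(0.1, 3, 42)) {
    spec_k <- spec
    spec_k$weight <- spec$weight * k
    expect_equal(composite_desirability(c(x1 = 0), sf, spec_k)$value, base,
                 tolerance = 1e-12)
  }
})

test_that("degenerate composite specifications are rejected", {
  expect_error(composite_spec("a", "NTB", lsl = 1, target = 2, usl = 3,
                              weight = 0),
               class = "releaseopt_schema_error")
  sf <- surfaces_for_composite(list(a = 30))
  spec <- composite_spec("missing", "NTB", lsl = 20, target = 30, usl = 40)
  expect_error(composite_desirability(c(x1 = 0), sf, spec),
               class = "releaseopt_schema_error")
})

test_that("negative fitted dispersion values clamp to zero with a warning", {
  sf <- list(v = response_surface(c("1" = -2), role = "variance",
                                  label = "y1"))
  spec <- composite_spec("v", "STB", lsl = 0, usl = 10, clamp = TRUE)
  expect_warning(res <- composite_desirability(c(x1 = 0), sf, spec),
                 class = "releaseopt_clamp_warning")
  expect_equal(res$breakdown$desirability, 1)
})
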
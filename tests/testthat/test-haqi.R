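test_that("a noiseless linear world is identified exactly", {
  haqi <- seq(50, 95, by = 5)
  pts <- data.frame(haqi = haqi, coverage = 0.01 * (haqi - 44.1))
  m <- fit_coverage_haqi(pts, n_draws = 20)
  expect_equal(m$form, "linear")
  expect_equal(unname(m$rmse["linear"]), 0, tolerance = 1e-12)
  expect_equal(m$haqi0, rep(44.1, 20), tolerance = 1e-9)
  # two points define the line: (50, 0) and (100, 0.5)
  m2 <- fit_coverage_haqi(data.frame(haqi = c(50, 100), coverage = c(0, 0.5)),
                          n_draws = 5)
  expect_equal(m2$haqi0, rep(50, 5), tolerance = 1e-9)
})

test_that("adding a constant to coverage shifts the intercept left", {
  haqi <- seq(50, 95, by = 5)
  pts <- data.frame(haqi = haqi, coverage = 0.01 * (haqi - 44.1))
  shifted <- transform(pts, coverage = coverage + 0.1)
  m0 <- fit_coverage_haqi(pts, n_draws = 5)
  m1 <- fit_coverage_haqi(shifted, n_draws = 5)
  expect_equal(mean(m1$haqi0), mean(m0$haqi0) - 0.1 / 0.01, tolerance = 1e-9)
})

test_that("decreasing coverage and degenerate spans are rejected", {
  haqi <- seq(50, 90, by = 10)
  expect_error(fit_coverage_haqi(data.frame(haqi = haqi,
                                            coverage = 0.9 - 0.005 * haqi)),
               "not increasing")
  expect_error(fit_coverage_haqi(data.frame(haqi = c(50, 52, 54),
                                            coverage = c(0.1, 0.2, 0.3))),
               "span")
})

test_that("the intercept is recovered from noisy generator data", {
  cfg <- world_config(seed = 13)
  m <- fit_coverage_haqi(generate_coverage_points(cfg), n_draws = 500)
  expect_equal(m$form, "linear")
  expect_lt(abs(mean(m$haqi0) - 44.1), 3)
})

point_dist <- function(props, n_draws, hs) {
  P <- matrix(rep(props, each = n_draws), nrow = n_draws,
              dimnames = list(NULL, c("asymptomatic", "mild", "moderate", "severe")))
  anxburden:::new_severity_distribution(P, hs)
}

test_that("interpolation is exact at the anchors and plateaus below HAQI0", {
  D <- 40
  hs <- point_health_states(n_draws = D)
  anchor <- point_dist(c(0.23, 0.295, 0.293, 0.182), D, hs)
  notx <- point_dist(c(0.0, 0.437, 0.300, 0.263), D, hs)
  interp <- build_interpolator(anchor, notx, rep(88, D), rep(44.1, D))
  expect_equal(severity_at_haqi(interp, 88)$proportions, anchor$proportions,
               tolerance = 1e-12)
  for (h in c(44.1, 30, 0))
    expect_equal(severity_at_haqi(interp, h)$proportions, notx$proportions,
                 tolerance = 1e-12)
  # midpoint of the severe share before renormalisation
  mid <- severity_at_haqi(interp, (88 + 44.1) / 2)
  expect_equal(unname(mid$proportions[1, "severe"]), (0.182 + 0.263) / 2,
               tolerance = 1e-9)
  # identical endpoints make the interpolator constant
  flat <- build_interpolator(anchor, anchor, rep(88, D), rep(44.1, D))
  for (h in c(0, 50, 88, 100))
    expect_equal(severity_at_haqi(flat, h)$proportions, anchor$proportions,
                 tolerance = 1e-12)
  expect_error(build_interpolator(anchor, notx, rep(88, D), rep(90, D)),
               "does not exceed")
  expect_error(build_interpolator(anchor, notx, rep(88, 10), rep(44.1, D)),
               "draw count mismatch")
})

test_that("queries stay on the simplex, including under extrapolation", {
  D <- 30
  hs <- health_state_set(n_draws = D, seed = 5)
  anchor <- point_dist(c(0.23, 0.295, 0.293, 0.182), D, hs)
  notx <- point_dist(c(0.0, 0.437, 0.300, 0.263), D, hs)
  interp <- build_interpolator(anchor, notx, rep(88, D), rep(44.1, D))
  set.seed(2)
  for (h in runif(50, 0, 100)) {
    p <- severity_at_haqi(interp, h)$proportions
    expect_true(all(abs(rowSums(p) - 1) < 1e-9))
    expect_true(all(p >= 0 & p <= 1))
  }
  # beyond the anchor the asymptomatic share keeps growing but stays in [0, 1]
  p100 <- severity_at_haqi(interp, 100)$proportions
  expect_true(all(p100 >= 0 & p100 <= 1))
  expect_gt(p100[1, "asymptomatic"], anchor$proportions[1, "asymptomatic"])
})

test_that("the sequela-weighted DW falls as access improves", {
  D <- 20
  hs <- point_health_states(n_draws = D)
  anchor <- point_dist(c(0.23, 0.295, 0.293, 0.182), D, hs)
  notx <- point_dist(c(0.0, 0.437, 0.300, 0.263), D, hs)
  interp <- build_interpolator(anchor, notx, rep(88, D), rep(44.1, D))
  dws <- vapply(seq(20, 100, by = 10),
                function(h) severity_at_haqi(interp, h)$dw[1], numeric(1))
  expect_true(all(diff(dws) <= 1e-12))
})
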
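test_that("gaze speeds match a per-pair loop oracle", {
  tr0 <- gaze_trace(seq(0, 0.08, by = 0.02), rep(1, 5), rep(2, 5))
  expect_equal(gaze_speeds(tr0), rep(0, 4))
  tr1 <- gaze_trace(seq(0, by = 0.02, length.out = 6),
                    seq(0, by = 0.1, length.out = 6), rep(0, 6))
  expect_equal(gaze_speeds(tr1), rep(5, 5))
  set.seed(5)
  tr2 <- gaze_trace(seq(0, by = 0.02, length.out = 50),
                    runif(50, 0, 5), runif(50, 0, 4))
  oracle <- sapply(2:50, function(i)
    sqrt((tr2$x_deg[i] - tr2$x_deg[i - 1])^2 +
           (tr2$y_deg[i] - tr2$y_deg[i - 1])^2) / 0.02)
  expect_equal(gaze_speeds(tr2), oracle, tolerance = 1e-12)
  expect_error(gaze_trace(c(0, 0.02, 0.05), 1:3, 1:3), "uniform")
})

test_that("speed filtering invalidates exactly the super-threshold samples", {
  tr <- gaze_trace(seq(0, by = 0.02, length.out = 5),
                   c(0, 0.05, 0.1, 0.15, 0.2), rep(0, 5))
  expect_identical(filter_speed(tr)$valid, rep(TRUE, 5))
  # one 387 deg/s jump into sample 4; the trace continues slowly after it
  jump <- tr
  jump$x_deg[4] <- jump$x_deg[3] + 387 * 0.02
  jump$x_deg[5] <- jump$x_deg[4] + 0.05
  filt <- filter_speed(jump)
  expect_identical(which(!filt$valid), 4L)
  expect_equal(sum(!filt$valid), sum(gaze_speeds(jump) > 5))
  # disabling the exclusion keeps everything (the robustness re-analysis)
  expect_identical(filter_speed(jump, vmax = Inf)$valid, rep(TRUE, 5))
  expect_error(filter_speed(tr, vmax = 0), "positive")
})

test_that("cumulative speed fractions behave as an ecdf", {
  set.seed(8)
  tr <- gaze_trace(seq(0, by = 0.02, length.out = 100),
                   cumsum(runif(100, 0, 0.1)), rep(0, 100))
  sp <- gaze_speeds(tr)
  expect_equal(cumulative_speed_fraction(tr, max(sp)), 1.0)
  expect_equal(cumulative_speed_fraction(tr, 0), 0.0)
  expect_equal(cumulative_speed_fraction(tr, median(sp)),
               mean(sp <= median(sp)))
})

test_that("random gaze is uniform, seeded, and frame-counted", {
  cfg <- walk_config(duration_s = 300, interval_s = 0.02,
                     bounds = c(6.9, 5.3), seed = 21)
  tr <- simulate_random_gaze(cfg)
  expect_length(tr, 15000)
  expect_identical(simulate_random_gaze(cfg)$x_deg, tr$x_deg)
  expect_true(all(tr$x_deg >= 0 & tr$x_deg <= 6.9))
  expect_true(all(tr$y_deg >= 0 & tr$y_deg <= 5.3))
  # chi-square uniformity on a 4 x 4 grid
  gx <- cut(tr$x_deg, seq(0, 6.9, length.out = 5))
  gy <- cut(tr$y_deg, seq(0, 5.3, length.out = 5))
  p <- chisq.test(table(gx, gy))$p.value
  expect_gt(p, 0.01)
})

test_that("the random walk takes exactly fixed steps inside the bounds", {
  cfg <- walk_config(step_speed_degps = 2.3, duration_s = 60,
                     bounds = c(6.9, 5.3), seed = 4)
  tr <- simulate_random_walk(cfg)
  steps <- sqrt(diff(tr$x_deg)^2 + diff(tr$y_deg)^2)
  expect_lt(max(abs(steps - 2.3 * 0.02)), 1e-9)
  expect_true(all(tr$x_deg >= 0 & tr$x_deg <= 6.9))
  expect_true(all(tr$y_deg >= 0 & tr$y_deg <= 5.3))
  expect_error(
    simulate_random_walk(walk_config(step_speed_degps = 1000,
                                     duration_s = 1, bounds = c(6.9, 5.3))),
    "step larger")
})

test_that("walk mean squared displacement grows linearly at small lags", {
  r2s <- sapply(1:10, function(s) {
    cfg <- walk_config(step_speed_degps = 2.3, duration_s = 40,
                       bounds = c(30, 25), seed = 100 + s,
                       start = c(15, 12.5))
    tr <- simulate_random_walk(cfg)
    lags <- 1:20
    msd <- sapply(lags, function(L)
      mean((tr$x_deg[-(1:L)] - head(tr$x_deg, -L))^2 +
             (tr$y_deg[-(1:L)] - head(tr$y_deg, -L))^2))
    summary(lm(msd ~ lags))$r.squared
  })
  expect_gte(mean(r2s >= 0.95), 0.9)
})

test_that("the local-feature walk locks onto the most chromatic region", {
  # gray scene with one saturated red-reflecting patch
  grid <- canonical_grid()
  red <- ifelse(grid >= 590, 0.9, 0.05)
  data <- array(0.4, c(20, 24, length(grid)))
  for (b in seq_along(grid))
    data[9:13, 15:19, b] <- red[b]
  scene <- spectral_image(data, grid, kind = "reflectance",
                          degrees_per_pixel = 0.1)
  cfg <- walk_config(step_speed_degps = 0.77, duration_s = 10,
                     bounds = c(2.4, 2.0), seed = 6)
  tr <- simulate_local_feature(scene, cfg)
  center <- c((17 - 0.5) * 0.1, (11 - 0.5) * 0.1)
  d <- sqrt((tr$x_deg - center[1])^2 + (tr$y_deg - center[2])^2)
  expect_lt(max(d), 0.25 + 1e-9)

  # uniform scene: tie broken by the first window in row-major order
  uni <- spectral_image(array(0.4, c(12, 12, length(grid))), grid,
                        kind = "reflectance", degrees_per_pixel = 0.1)
  tru <- simulate_local_feature(uni, cfg)
  expect_equal(c(tru$x_deg[1], tru$y_deg[1]), c(0.25, 0.25))
  expect_error(simulate_local_feature(
    spectral_image(array(0.4, c(4, 4, length(grid))), grid,
                   kind = "reflectance", degrees_per_pixel = 0.1), cfg),
    "5 x 5")
})

test_that("gaze CSV round trips", {
  tr <- gaze_trace(seq(0, 0.08, by = 0.02), 1:5 / 10, 5:1 / 10,
                   c(TRUE, TRUE, FALSE, TRUE, TRUE))
  p <- file.path(tempdir(), "gaze.csv")
  write_gaze(tr, p)
  back <- read_gaze(p)
  expect_equal(back$x_deg, tr$x_deg)
  expect_identical(back$valid, tr$valid)
})
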
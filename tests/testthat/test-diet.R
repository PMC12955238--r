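test_that("Freedman-Diaconis bin counts match the direct formula", {
  expect_equal(fd_bin_count(rep(3.2, 10)), 1L)
  x <- 1:8
  iqr <- unname(diff(quantile(x, c(0.25, 0.75), type = 7)))
  oracle <- ceiling((max(x) - min(x)) / (2 * iqr * 8^(-1 / 3)))
  expect_equal(fd_bin_count(x), as.integer(oracle))
  expect_error(fd_bin_count(1), "at least 2")
  # n^(-1/3) scaling: more samples from the same distribution never
  # shrinks the bin count beyond rounding, in trend over 10 draws
  set.seed(13)
  grows <- replicate(10, {
    a <- rnorm(300); b <- c(a, rnorm(300))
    fd_bin_count(b) >= fd_bin_count(a) - 1
  })
  expect_true(all(grows))
})

test_that("matched histograms share edges, normalize, and respect support", {
  set.seed(4)
  x <- rnorm(500)
  mh <- matched_histograms(x, x)
  expect_identical(mh$local$edges, mh$global$edges)
  expect_equal(sum(mh$local$rel_freq), 1, tolerance = 1e-12)
  expect_equal(sum(mh$global$rel_freq), 1, tolerance = 1e-12)
  expect_equal(local_global_r(mh$local, mh$global), 1)
  expect_equal(length(mh$local$rel_freq), fd_bin_count(x))

  # local support confined to a narrow subrange of the global samples
  g <- runif(2000, 0, 10)
  l <- runif(200, 4, 5)
  mh2 <- matched_histograms(l, g)
  outside <- mh2$local$edges[-1] < 4 | utils::head(mh2$local$edges, -1) > 5
  expect_true(all(mh2$local$rel_freq[outside] == 0))
  expect_error(matched_histograms(l, numeric(0)), "empty")
})

test_that("histogram correlation matches the textbook formula and flags degeneracy", {
  two <- function(p) structure(list(edges = c(0, 1, 2), rel_freq = p,
                                    n = 10, cone_class = "L"),
                               class = "diet_histogram")
  expect_equal(local_global_r(two(c(0.8, 0.2)), two(c(0.2, 0.8))), -1)
  set.seed(3)
  e <- seq(0, 1, length.out = 11)
  a <- runif(10); a <- a / sum(a)
  b <- runif(10); b <- b / sum(b)
  ha <- structure(list(edges = e, rel_freq = a, n = 1, cone_class = "L"),
                  class = "diet_histogram")
  hb <- structure(list(edges = e, rel_freq = b, n = 1, cone_class = "L"),
                  class = "diet_histogram")
  loop_r <- {
    ma <- mean(a); mb <- mean(b)
    num <- 0; da <- 0; db <- 0
    for (i in 1:10) {
      num <- num + (a[i] - ma) * (b[i] - mb)
      da <- da + (a[i] - ma)^2; db <- db + (b[i] - mb)^2
    }
    num / sqrt(da * db)
  }
  expect_equal(local_global_r(ha, hb), loop_r, tolerance = 1e-12)
  hc <- structure(list(edges = e, rel_freq = rep(0.1, 10), n = 1,
                       cone_class = "L"), class = "diet_histogram")
  expect_true(is.na(local_global_r(ha, hc)))
  expect_error(local_global_r(ha, two(c(0.5, 0.5))), "edges")
})

test_that("the correlation curve equals a from-scratch recomputation at random end frames", {
  fx <- get_fixtures(duration_s = 20, height = 36, width = 48)
  sc <- fx$scenes$high_var
  cones <- cone_excitations(apply_illuminant(sc, fx$illuminants$ref))
  ser <- foveal_series(cones, fx$traces$random)
  cv <- correlation_curve(ser, cones, start = 50, stop = nrow(ser))
  set.seed(99)
  checks <- sample(length(cv$end_frames), 5)
  for (ci in 1:3) {
    gmax <- max(list(cones$qL, cones$qM, cones$qS)[[ci]])
    gall <- log10(pmax(as.numeric(list(cones$qL, cones$qM,
                                       cones$qS)[[ci]]),
                       1e-6 * gmax))
    lall <- log10(pmax(ser[, ci], 1e-6 * gmax))
    for (k in checks) {
      n <- cv$end_frames[k]
      mh <- matched_histograms(lall[1:n], gall)
      expect_equal(unname(cv$r[k, ci]),
                   local_global_r(mh$local, mh$global),
                   tolerance = 1e-12)
    }
  }
})

test_that("degenerate and truncated series are handled honestly", {
  img <- cone_image(matrix(0.5, 8, 8), matrix(0.5, 8, 8),
                    matrix(0.5, 8, 8), degrees_per_pixel = 0.5)
  tr <- gaze_trace(seq(0, by = 0.02, length.out = 120),
                   rep(2, 120), rep(2, 120))
  ser <- foveal_series(img, tr)
  cv <- correlation_curve(ser, img, start = 50, stop = 120)
  expect_true(all(is.na(cv$r)))
  expect_warning(correlation_curve(ser, img, start = 50, stop = 500),
                 "truncat")
  expect_error(correlation_curve(ser[1:10, ], img, start = 50, stop = 10),
               "shorter")
})

test_that("curve averaging matches a loop oracle and handles agreement", {
  mk <- function(rvals) structure(list(end_frames = 1:4,
                                       times_s = (1:4) * 0.02,
                                       r = cbind(L = rvals, M = rvals,
                                                 S = rvals),
                                       meta = list()),
                                  class = "correlation_curve")
  same <- average_curves(list(mk(c(.1, .2, .3, .4)), mk(c(.1, .2, .3, .4))))
  expect_true(all(same$se == 0))
  ab <- average_curves(list(mk(rep(0.2, 4)), mk(rep(0.4, 4))))
  expect_equal(unname(ab$mean[1, "L"]), 0.3)
  expect_equal(unname(ab$se[1, "L"]), 0.1)
  set.seed(17)
  curves <- lapply(1:5, function(i) mk(runif(4)))
  avg <- average_curves(curves)
  vals <- sapply(curves, function(cv) cv$r[3, "M"])
  expect_equal(unname(avg$mean[3, "M"]), mean(vals), tolerance = 1e-12)
  expect_equal(unname(avg$se[3, "M"]), sd(vals) / sqrt(5),
               tolerance = 1e-12)
  expect_error(average_curves(list()), "no curves")
})

test_that("human-like gaze shows the rising convergence trend of the statistic", {
  fx <- get_fixtures(duration_s = 60, height = 72, width = 96)
  d <- spectral_diet(fx$scenes$high_var, fx$traces$human_like,
                     illuminant = fx$illuminants$ref)
  n <- nrow(d$curve$r)
  early <- colMeans(d$curve$r[1:100, ], na.rm = TRUE)
  late <- apply(d$curve$r[(n - 99):n, ], 2, median, na.rm = TRUE)
  expect_true(all(late > early))
  expect_true(all(late > 0.9))
})
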
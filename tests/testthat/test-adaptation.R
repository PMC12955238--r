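test_that("exponential history weights have their closed forms", {
  expect_equal(exponential_weights(0.5, 0.5, 1), 1)
  w <- exponential_weights(c(0, 1), 1, 1)
  expect_equal(w[2] / w[1], exp(1), tolerance = 1e-12)
  expect_equal(sum(w), 1)
  wu <- exponential_weights(seq(0, 10, by = 1), 10, 1e9)
  expect_lt(diff(range(wu)), 1e-6 * max(wu))
  expect_error(exponential_weights(numeric(0), 0, 1), "empty")
  expect_error(exponential_weights(0, 1, -1), "tau")
})

test_that("the local adaptation field is the weighted history reciprocal", {
  mkframe <- function(val, t) list(rgb = array(val, c(4, 4, 3)), time_s = t)
  f <- local_adaptation_field(list(mkframe(0.5, 0), mkframe(0.5, 1)),
                              tau_s = 1)
  expect_equal(as.numeric(f$gains), rep(2, 48), tolerance = 1e-12)
  single <- local_adaptation_field(list(mkframe(0.25, 0)), tau_s = 5)
  expect_equal(as.numeric(single$gains), rep(4, 48), tolerance = 1e-12)
  # two distinct frames: hand-computed weighted mean per pixel
  set.seed(21)
  a <- array(runif(48, 0.2, 1), c(4, 4, 3))
  b <- array(runif(48, 0.2, 1), c(4, 4, 3))
  f2 <- local_adaptation_field(list(list(rgb = a, time_s = 0),
                                    list(rgb = b, time_s = 1)),
                               now = 1, tau_s = 2)
  w <- exp(c(-0.5, 0)); w <- w / sum(w)
  expect_equal(as.numeric(f2$gains),
               as.numeric(1 / (w[1] * a + w[2] * b)), tolerance = 1e-12)
})

test_that("diagonal corrections behave as von Kries scalings", {
  set.seed(6)
  img <- array(runif(27, 0.1, 2), c(3, 3, 3))
  field <- structure(list(gains = 1 / img), class = "adaptation_field")
  expect_equal(as.numeric(diagonal_correct_local(img, field)),
               rep(1, 27), tolerance = 1e-15)
  ones <- structure(list(gains = array(1, c(3, 3, 3))),
                    class = "adaptation_field")
  expect_identical(diagonal_correct_local(img, ones), img)
  gains2 <- array(runif(27, 0.5, 2), c(3, 3, 3))
  expect_equal(as.numeric(diagonal_correct_local(img, gains2)),
               as.numeric(img * gains2), tolerance = 1e-15)

  g <- global_gains(img)
  corr <- diagonal_correct_global(img, g)
  expect_equal(apply(corr, 3, mean), rep(1, 3), tolerance = 1e-9)
  uni <- array(rep(c(0.4, 0.6, 0.8), each = 9), c(3, 3, 3))
  cu <- diagonal_correct_global(uni, global_gains(uni))
  expect_equal(as.numeric(cu), rep(1, 27), tolerance = 1e-12)
  # an illuminant acting diagonally in RGB is removed exactly
  d <- c(1.7, 0.8, 1.2)
  relit <- sweep(img, 3, d, "*")
  expect_equal(diagonal_correct_global(relit, global_gains(relit)),
               corr, tolerance = 1e-9)
  expect_error(diagonal_correct_global(img, c(1, 0, 1)), "positive")
})

test_that("median color differences are robust and hand-checkable", {
  vc <- viewing_conditions()
  img <- array(runif(27, 0.5, 1.5), c(3, 3, 3))
  expect_equal(median_delta_e(img, img, vc), 0)
  # single extreme outlier pixel does not move the median
  img2 <- img
  img2[1, 1, ] <- img[1, 1, ] * 3
  img3 <- img
  img3[1, 1, ] <- img[1, 1, ] * 30
  expect_equal(median_delta_e(img, img2, vc), median_delta_e(img, img3, vc))
  # 3-pixel toy: median equals the middle per-pixel difference
  a <- array(c(rep(1, 3), rep(1, 3), rep(1, 3)), c(3, 1, 3))
  b <- array(c(1, 1.1, 1.5, 1, 1.1, 1.5, 1, 1.1, 1.5), c(3, 1, 3))
  des <- sapply(1:3, function(i)
    delta_e_ucs(cam16_ucs_coords(a[i, 1, ], vc),
                cam16_ucs_coords(b[i, 1, ], vc)))
  expect_equal(median_delta_e(a, b, vc), sort(des)[2], tolerance = 1e-12)
})

test_that("evaluation frames are geometric from 3 to n-1", {
  idx <- evaluation_times(15000, 6, 3)
  expect_equal(idx[1], 3L)
  expect_equal(idx[length(idx)], 14999L)
  expect_equal(evaluation_times(15000, 2, 3), c(3L, 14999L))
  ratios <- idx[-1] / utils::head(idx, -1)
  expect_lt(diff(range(log(ratios))), 0.1)
  expect_error(evaluation_times(10, 20, 3), "count")
})

test_that("a spatially uniform scene gives zero local-global difference", {
  fx <- get_fixtures(duration_s = 20, height = 36, width = 48)
  ac <- adaptation_timecourse(fx$scenes$uniform, fx$traces$random,
                              tau_s = 1, count = 4)
  expect_lt(max(ac$median_dE), 1e-8)
})

test_that("confined gaze leaves a larger residual than uniform gaze", {
  fx <- get_fixtures(duration_s = 20, height = 36, width = 48)
  sc <- fx$scenes$high_var
  a_rand <- adaptation_timecourse(sc, fx$traces$random, tau_s = 1e9,
                                  count = 4)
  a_feat <- adaptation_timecourse(sc, fx$traces$feature, tau_s = 1e9,
                                  count = 4)
  last <- length(a_rand$median_dE)
  expect_gt(a_feat$median_dE[last], a_rand$median_dE[last])
  # with effectively infinite memory the residual shrinks from the first
  # to the last evaluation under uniform sampling
  expect_lt(a_rand$median_dE[last], a_rand$median_dE[1])
})

test_that("uncorrected illuminant shifts grow with the CCT gap", {
  fx <- get_fixtures(duration_s = 20, height = 36, width = 48)
  sc <- fx$scenes$high_var
  same <- uncorrected_delta_e(sc, daylight_spd(4000), 4000)
  expect_lt(same, 1e-9)
  small_gap <- uncorrected_delta_e(sc, daylight_spd(6500), 5500)
  big_gap <- uncorrected_delta_e(sc, daylight_spd(10000), 4000)
  expect_gt(big_gap, small_gap)
  # achromatic flat scene: the difference map is uniform
  grid <- canonical_grid()
  flat <- spectral_image(array(0.5, c(6, 6, length(grid))), grid,
                         kind = "reflectance", degrees_per_pixel = 0.5)
  vc <- viewing_conditions(
    white_rgb = xyz_to_cam16_rgb(spd_to_xyz(daylight_spd(6504))))
  r1 <- xyz_to_cam16_rgb(cube_to_xyz(apply_illuminant(flat,
                                                      daylight_spd(6504))))
  r2 <- xyz_to_cam16_rgb(cube_to_xyz(apply_illuminant(flat,
                                                      daylight_spd(4000))))
  de <- delta_e_ucs(cam16_ucs_coords(r1, vc), cam16_ucs_coords(r2, vc))
  expect_lt(diff(range(de)), 1e-9)
  expect_equal(uncorrected_delta_e(flat, daylight_spd(6504), 4000,
                                   vc = vc),
               de[1, 1], tolerance = 1e-9)
})

test_that("the weighted-history estimate converges to the global mean under uniform sampling", {
  # spatially stationary fine-grain mosaic, so the whole-image mean is
  # also the mean seen through the mirror-padded 5-degree window
  sc <- make_scene(scene_spec(72, 96, n_patches = 300, chroma_spread = 0.2,
                              seed = 11))
  rgb <- xyz_to_cam16_rgb(cube_to_xyz(apply_illuminant(sc,
                                                       daylight_spd(5571))))
  gmu <- apply(rgb, 3, mean)
  s <- gazediet:::.retinal_sampler(list(rgb[, , 1], rgb[, , 2],
                                        rgb[, , 3]),
                                   sc$degrees_per_pixel)
  set.seed(9)
  n <- 10000
  dpp <- sc$degrees_per_pixel
  px <- gazediet:::.gaze_pixel(runif(n, 0, 96 * dpp), runif(n, 0, 72 * dpp),
                               dpp, 72, 96)
  acc <- 0
  for (k in seq_len(n)) {
    p <- gazediet:::.sampler_patch(s, px[k, 1], px[k, 2])
    acc <- acc + array(c(p[[1]], p[[2]], p[[3]]),
                       c(nrow(p[[1]]), ncol(p[[1]]), 3))
  }
  state <- acc / n   # equal weights: the tau -> infinity limit
  for (ch in 1:3) {
    rel_err <- abs(state[, , ch] - gmu[ch]) / gmu[ch]
    expect_lt(mean(rel_err[s$mask]), 0.05)
  }
})
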
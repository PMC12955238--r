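test_that("cone excitations are zero for zero input, linear, and match a loop oracle", {
  grid <- canonical_grid()
  f <- cone_fundamentals()
  zero <- spectrum(grid, rep(0, length(grid)))
  expect_equal(unname(cone_excitations(zero, f)), c(0, 0, 0))

  set.seed(7)
  v <- runif(length(grid), 0, 2)
  s1 <- spectrum(grid, v)
  s2 <- spectrum(grid, 2 * v)
  expect_equal(cone_excitations(s2, f), 2 * cone_excitations(s1, f),
               tolerance = 1e-12)

  flat <- spectrum(grid, rep(1, length(grid)))
  q <- cone_excitations(flat, f)
  expect_equal(unname(q), unname(10 * colSums(f$s)), tolerance = 1e-12)
  expect_equal(unname(cone_excitations(s1, f)),
               loop_cone_excitations(v, f$s), tolerance = 1e-12)

  # image form agrees with the per-spectrum form pixelwise
  cube <- tiny_cube(4, 3)
  ci <- cone_excitations(cube, f)
  px <- cone_excitations(spectrum(grid, cube$data[2, 3, ]), f)
  expect_equal(c(ci$qL[2, 3], ci$qM[2, 3], ci$qS[2, 3]), unname(px),
               tolerance = 1e-12)
})

test_that("cone excitation validation rejects bad inputs", {
  expect_error(spectrum(canonical_grid(), rep(-1, 33)), "nonnegative")
  expect_error(spectrum(c(400, 400, 410), c(1, 1, 1)), "increasing")
})

test_that("daylight SPDs are physical and redder at low CCT", {
  d40 <- daylight_spd(4000)
  expect_true(all(is.finite(d40$values)) && all(d40$values >= 0))
  d100 <- daylight_spd(10000)
  ratio <- function(s) {
    long <- sum(s$values[s$wavelengths_nm >= 600])
    short <- sum(s$values[s$wavelengths_nm <= 480])
    long / short
  }
  expect_gt(ratio(d40), ratio(d100))
  expect_error(daylight_spd(3000), "cct")
  expect_error(daylight_spd(30000), "cct")
})

test_that("XYZ integration is linear and equal-energy maps near (1/3, 1/3)", {
  grid <- canonical_grid()
  zero <- spectrum(grid, rep(0, length(grid)))
  expect_equal(unname(spd_to_xyz(zero)), c(0, 0, 0))
  set.seed(2)
  v <- runif(length(grid))
  expect_equal(spd_to_xyz(spectrum(grid, 3 * v)),
               3 * spd_to_xyz(spectrum(grid, v)), tolerance = 1e-12)
  ee <- spd_to_xyz(spectrum(grid, rep(1, length(grid))))
  xy <- ee[1:2] / sum(ee)
  expect_lt(max(abs(xy - 1 / 3)), 0.005)
  # summation oracle
  cmf <- cie_cmf(grid)
  expect_equal(unname(spd_to_xyz(spectrum(grid, v))),
               as.numeric(t(cmf) %*% v * 10), tolerance = 1e-12)
})

test_that("daylight CCT round-trips within 50 K and is monotone", {
  for (cct in c(4000, 5500, 6504, 8000, 10000)) {
    est <- cct_of(spd_to_xyz(daylight_spd(cct)))
    expect_lt(abs(est - cct), 50)
  }
  ests <- sapply(c(4000, 5500, 7500), function(t)
    cct_of(spd_to_xyz(daylight_spd(t))))
  expect_true(all(diff(ests) > 0))
  # far off the locus: a nearly pure-red stimulus
  expect_error(cct_of(c(80, 20, 1)), "locus")
})

test_that("illuminant application and division round-trip", {
  cube <- tiny_cube()
  ill <- daylight_spd(5500)
  rad <- apply_illuminant(cube, ill)
  expect_identical(rad$kind, "radiance")
  back <- radiance_to_reflectance(rad, ill)
  expect_identical(back$kind, "reflectance")
  expect_lt(max(abs(back$data - cube$data) / pmax(cube$data, 1e-12)), 1e-10)

  ones <- spectral_image(array(1, dim(cube$data)), cube$wavelengths_nm,
                         kind = "reflectance", degrees_per_pixel = 0.1)
  rad1 <- apply_illuminant(ones, ill)
  expect_equal(rad1$data[3, 5, ], ill$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  zero_ref <- spectrum(canonical_grid(),
                       c(0, rep(1, 32)))
  expect_error(radiance_to_reflectance(rad, zero_ref), "positive")
})

test_that("CIELAB chroma is zero for achromatic stimuli and matches the cube-root formula", {
  white <- spd_to_xyz(daylight_spd(6504))
  expect_equal(lab_chroma(0.37 * white, white), 0, tolerance = 1e-9)
  xyz <- c(30, 40, 20)
  expect_equal(lab_chroma(xyz, white), lab_chroma(2 * xyz, 2 * white),
               tolerance = 1e-9)
  # hand-computed via the standard f() with cube root
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  a <- 500 * (f(xyz[1] / white[1]) - f(xyz[2] / white[2]))
  b <- 200 * (f(xyz[2] / white[2]) - f(xyz[3] / white[3]))
  expect_equal(lab_chroma(xyz, white), unname(sqrt(a^2 + b^2)),
               tolerance = 1e-9)
  expect_error(lab_chroma(xyz, c(1, 0, 1)), "Y > 0")
})
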
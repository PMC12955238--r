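#' Synthetic scene specification
#'
#' Parameters for [make_scene()]: a Voronoi mosaic of chromatic regions
#' whose reflectances are nonnegative combinations of smooth raised-cosine
#' spectral basis functions, emulating the piecewise-smooth structure of
#' natural reflectance scenes with controllable chromatic variance.
#'
#' @param height,width Scene size in pixels (>= 8).
#' @param n_patches Number of chromatic regions (>= 1).
#' @param basis_dim Number of raised-cosine basis spectra (>= 3).
#' @param chroma_spread Scale of the basis-coefficient variance; 0 gives a
#'   spatially uniform gray scene.
#' @param shading_amp Amplitude of a smooth multiplicative shading field
#'   (low-frequency illumination/shape variation within regions, as in
#'   natural scenes). `NULL` resolves to 0.2 for chromatic scenes and to 0
#'   when `chroma_spread = 0`, keeping the degenerate scene exactly
#'   uniform.
#' @param seed RNG seed.
#' @param span_deg Horizontal angular span of the scene (deg); sets
#'   `degrees_per_pixel = span_deg / width` (camera-like default 6.9).
#' @return A list of class `"scene_spec"`.
#' @export
scene_spec <- function(height = 48, width = 64, n_patches = 8,
                       basis_dim = 6, chroma_spread = 0.15,
                       shading_amp = NULL, seed = 1L,
                       span_deg = 6.9) {
  if (height < 8 || width < 8) stop("scene must be at least 8 x 8 pixels")
  if (basis_dim < 3) stop("basis_dim must be >= 3")
  if (n_patches < 1) stop("need at least one region")
  if (chroma_spread < 0) stop("chroma_spread must be >= 0")
  if (is.null(shading_amp))
    shading_amp <- if (chroma_spread > 0) 0.2 else 0
  if (shading_amp < 0 || shading_amp >= 1)
    stop("shading_amp must be in [0, 1)")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_patches = as.integer(n_patches),
                 basis_dim = as.integer(basis_dim),
                 chroma_spread = chroma_spread, shading_amp = shading_amp,
                 seed = as.integer(seed), span_deg = span_deg),
            class = "scene_spec")
}

# raised-cosine bumps over the grid, centers 420-700 nm
.spectral_basis <- function(grid = canonical_grid(), basis_dim = 6) {
  centers <- seq(420, 700, length.out = basis_dim)
  halfwidth <- 1.6 * (centers[2] - centers[1])
  sapply(centers, function(c0) {
    d <- abs(grid - c0)
    ifelse(d <= halfwidth, 0.5 * (1 + cos(pi * d / halfwidth)), 0)
  })
}

#' Generate a synthetic reflectance scene
#'
#' Voronoi-tessellated chromatic regions; each region's reflectance is a
#' gray base plus a random nonnegative-clipped combination of smooth
#' raised-cosine basis spectra, clipped to [0, 1]. Seed-deterministic.
#'
#' @param spec A [scene_spec()].
#' @param grid Wavelength grid.
#' @return A reflectance `spectral_image`.
#' @export
make_scene <- function(spec, grid = canonical_grid()) {
  stopifnot(inherits(spec, "scene_spec"))
  basis <- .spectral_basis(grid, spec$basis_dim)
  .with_seed(spec$seed, function() {
    k <- spec$n_patches
    refl <- matrix(0, length(grid), k)
    for (j in seq_len(k)) {
      coefs <- stats::rnorm(spec$basis_dim, 0, spec$chroma_spread)
      refl[, j] <- pmin(pmax(0.35 + basis %*% coefs, 0.02), 1)
    }
    if (k == 1) {
      lab <- matrix(1L, spec$height, spec$width)
    } else {
      cx <- stats::runif(k, 0, spec$width)
      cy <- stats::runif(k, 0, spec$height)
      px <- outer(rep(1, spec$height), seq_len(spec$width) - 0.5)
      py <- outer(seq_len(spec$height) - 0.5, rep(1, spec$width))
      d2 <- array(Inf, c(spec$height, spec$width))
      lab <- matrix(1L, spec$height, spec$width)
      for (j in seq_len(k)) {
        dj <- (px - cx[j])^2 + (py - cy[j])^2
        upd <- dj < d2
        lab[upd] <- j
        d2[upd] <- dj[upd]
      }
    }
    shade <- matrix(1, spec$height, spec$width)
    if (spec$shading_amp > 0) {
      # two low-frequency sinusoids with random phase/orientation
      u <- (seq_len(spec$width) - 0.5) / spec$width
      v <- (seq_len(spec$height) - 0.5) / spec$height
      ph <- stats::runif(4, 0, 2 * pi)
      shade <- 1 + spec$shading_amp * 0.5 *
        (outer(sin(2 * pi * v + ph[1]), cos(2 * pi * u + ph[2]), "+") / 2 +
           outer(sin(4 * pi * v + ph[3]), sin(4 * pi * u + ph[4]), "*") / 2)
    }
    data <- array(0, c(spec$height, spec$width, length(grid)))
    for (b in seq_along(grid)) data[, , b] <- pmin(refl[b, lab] * shade, 1)
    spectral_image(data, grid, kind = "reflectance",
                   degrees_per_pixel = spec$span_deg / spec$width)
  })
}

#' Synthetic gaze specification
#'
#' Parameters for [make_gaze()]: a two-state trace mixing slow drift-like
#' shifts with occasional fast saccades, tuned so the fraction of speeds
#' below 5 deg/s matches `slow_fraction` (recorded gaze has ~80% or more
#' of shifts below that).
#'
#' @param duration_s Trace duration (s), default 300.
#' @param interval_s Sampling interval (s), default 0.02 (50 Hz).
#' @param slow_fraction Target fraction of speeds below 5 deg/s.
#' @param slow_speed_scale Typical slow speed (deg/s), default 2.3 (the
#'   recorded modal speed).
#' @param saccade_speed_scale Typical saccade speed (deg/s); 0 suppresses
#'   saccades entirely.
#' @param seed RNG seed.
#' @return A list of class `"gaze_spec"`.
#' @export
gaze_spec <- function(duration_s = 300, interval_s = 0.02,
                      slow_fraction = 0.8, slow_speed_scale = 2.3,
                      saccade_speed_scale = 60, seed = 1L) {
  if (slow_fraction <= 0 || slow_fraction >= 1)
    stop("slow_fraction must be in (0, 1)")
  if (slow_speed_scale <= 0 || slow_speed_scale >= 5)
    stop("slow_speed_scale must be positive and below the 5 deg/s threshold")
  if (saccade_speed_scale != 0 && saccade_speed_scale <= 5)
    stop("saccade_speed_scale must be 0 or above 5 deg/s")
  n <- duration_s / interval_s
  if (abs(n - round(n)) > 1e-9)
    stop("duration must be an integral number of intervals")
  structure(list(duration_s = duration_s, interval_s = interval_s,
                 slow_fraction = slow_fraction,
                 slow_speed_scale = slow_speed_scale,
                 saccade_speed_scale = saccade_speed_scale,
                 seed = as.integer(seed)),
            class = "gaze_spec")
}

#' Generate a synthetic gaze trace
#'
#' Two-state speed process: each step is a saccade with probability
#' `1 - slow_fraction` (speed lognormal around `saccade_speed_scale`,
#' truncated above 5 deg/s) and a slow shift otherwise (speed folded
#' normal around `slow_speed_scale`, truncated below 5 deg/s). Directions
#' are uniform and redrawn until the step stays inside the bounds.
#'
#' @param spec A [gaze_spec()].
#' @param bounds Image angular extent `c(width_deg, height_deg)`.
#' @return A `gaze_trace` with `duration_s / interval_s` samples.
#' @export
make_gaze <- function(spec, bounds) {
  stopifnot(inherits(spec, "gaze_spec"))
  if (length(bounds) != 2 || any(bounds <= 0))
    stop("bounds must be positive c(width_deg, height_deg)")
  n <- as.integer(round(spec$duration_s / spec$interval_s))
  dt <- spec$interval_s
  .with_seed(spec$seed, function() {
    x <- numeric(n); y <- numeric(n)
    x[1] <- stats::runif(1) * bounds[1]
    y[1] <- stats::runif(1) * bounds[2]
    is_sac <- if (spec$saccade_speed_scale == 0) rep(FALSE, n - 1)
              else stats::runif(n - 1) > spec$slow_fraction
    for (i in seq_len(n - 1)) {
      sp <- if (is_sac[i]) {
        max(5.5, stats::rlnorm(1, log(spec$saccade_speed_scale), 0.4))
      } else {
        min(4.9, abs(stats::rnorm(1, spec$slow_speed_scale,
                                  spec$slow_speed_scale / 2)))
      }
      step <- sp * dt
      if (step > min(bounds) / 2) step <- min(bounds) / 2
      repeat {
        th <- stats::runif(1, 0, 2 * pi)
        nx <- x[i] + step * cos(th)
        ny <- y[i] + step * sin(th)
        if (nx >= 0 && nx <= bounds[1] && ny >= 0 && ny <= bounds[2]) break
      }
      x[i + 1] <- nx; y[i + 1] <- ny
    }
    trace <- gaze_trace(seq(0, by = dt, length.out = n), x, y)
    frac <- cumulative_speed_fraction(trace, 5)
    if (abs(frac - spec$slow_fraction) > 0.03 &&
        spec$saccade_speed_scale != 0)
      warning(sprintf("sub-5 deg/s fraction %.3f misses target %.2f",
                      frac, spec$slow_fraction))
    trace
  })
}

#' Canonical synthetic fixture bundle
#'
#' A small seed-deterministic bundle exercising every analysis stage:
#' a uniform gray scene, a two-region scene, a high-variance mosaic scene;
#' daylight illuminants at 4000 K (the test illuminant) and 5571 K (the
#' mean scene illumination of the study); and one gaze trace per model
#' (synthetic human-like, random gaze, random walk, local feature) over
#' the high-variance scene.
#'
#' @param seed Master seed; sub-seeds are derived from it.
#' @param duration_s Trace duration (s); default 60 keeps the bundle
#'   light for testing.
#' @param height,width Scene size in pixels.
#' @return A list with `scenes`, `illuminants`, `traces` and `bounds`.
#' @export
make_fixture_set <- function(seed = 1L, duration_s = 60,
                             height = 48, width = 64) {
  seeds <- .with_seed(seed, function() sample.int(2^31 - 1, 8))
  scenes <- list(
    uniform = make_scene(scene_spec(height, width, n_patches = 1,
                                    chroma_spread = 0, seed = seeds[1])),
    two_region = make_scene(scene_spec(height, width, n_patches = 2,
                                       chroma_spread = 0.3,
                                       shading_amp = 0, seed = seeds[2])),
    high_var = make_scene(scene_spec(height, width, n_patches = 12,
                                     chroma_spread = 0.25,
                                     seed = seeds[3])))
  bounds <- c(width, height) * scenes$high_var$degrees_per_pixel
  cfg <- function(s, speed = 2.3)
    walk_config(step_speed_degps = speed, duration_s = duration_s,
                bounds = bounds, seed = s)
  traces <- list(
    human_like = make_gaze(gaze_spec(duration_s = duration_s,
                                     seed = seeds[4]), bounds),
    random = simulate_random_gaze(cfg(seeds[5])),
    walk = simulate_random_walk(cfg(seeds[6])),
    feature = simulate_local_feature(scenes$high_var,
                                     cfg(seeds[7], speed = 0.77)))
  list(scenes = scenes,
       illuminants = list(d4000 = daylight_spd(4000),
                          ref = daylight_spd(5571)),
       traces = traces, bounds = bounds, seed = seed)
}
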
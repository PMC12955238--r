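#' Exponential history weights
#'
#' Weights for the cumulative adaptation estimate: w_k proportional to
#' exp(-(now - t_k) / tau), normalized to sum 1, so the most recent frame
#' carries the largest weight.
#'
#' @param frame_times Frame times (s), all <= `now`.
#' @param now Current time (s).
#' @param tau_s Adaptation time constant (s), > 0.
#' @return Normalized weight vector.
#' @export
exponential_weights <- function(frame_times, now, tau_s) {
  if (length(frame_times) == 0) stop("empty frame history")
  if (!is.finite(tau_s) || tau_s <= 0) stop("tau_s must be > 0")
  if (any(frame_times > now + 1e-12)) stop("frame times must not exceed now")
  w <- exp(-(now - frame_times) / tau_s)
  w / sum(w)
}

#' Local adaptation field from a retinal-frame history
#'
#' Per-pixel adaptation state at time `now`: the exponentially weighted
#' sum of the history's cone-like RGB retinal images; the diagonal gains
#' are the reciprocals of the weighted image, floored at `eps_frac` of the
#' per-channel maximum so dark pixels cannot produce unbounded gains.
#'
#' @param history List of frames, each a list with `rgb` (rows x cols x 3
#'   array, the blurred retinal patch in CAM16 RGB) and `time_s`.
#' @param now Evaluation time (s); defaults to the last frame time.
#' @param tau_s Time constant (s).
#' @param eps_frac Gain floor as a fraction of the channel maximum.
#' @return Object of class `"adaptation_field"`: `gains` array, `state`
#'   (the weighted RGB image), `tau_s`, `now`.
#' @export
local_adaptation_field <- function(history, now = NULL, tau_s = 1,
                                   eps_frac = 1e-6) {
  if (length(history) == 0) stop("empty frame history")
  times <- vapply(history, function(f) f$time_s, numeric(1))
  if (is.null(now)) now <- max(times)
  dims <- dim(history[[1]]$rgb)
  for (f in history)
    if (!identical(dim(f$rgb), dims)) stop("history frames differ in shape")
  w <- exponential_weights(times, now, tau_s)
  state <- array(0, dims)
  for (i in seq_along(history)) state <- state + w[i] * history[[i]]$rgb
  structure(list(gains = .reciprocal_gains(state, eps_frac), state = state,
                 tau_s = tau_s, now = now),
            class = "adaptation_field")
}

.reciprocal_gains <- function(state, eps_frac = 1e-6) {
  g <- state
  for (ch in 1:3) {
    m <- state[, , ch]
    floor_ <- eps_frac * max(abs(m))
    if (floor_ <= 0) floor_ <- eps_frac
    g[, , ch] <- 1 / pmax(m, floor_)
  }
  g
}

#' Local diagonal (von Kries) correction
#'
#' Elementwise product of a cone-like RGB image with per-pixel diagonal
#' gains: a pixel whose response equals its adaptation state maps to
#' (1, 1, 1).
#'
#' @param frame_rgb rows x cols x 3 array.
#' @param field An `"adaptation_field"` (or a bare gains array).
#' @return Corrected rows x cols x 3 array.
#' @export
diagonal_correct_local <- function(frame_rgb, field) {
  gains <- if (inherits(field, "adaptation_field")) field$gains else field
  if (!identical(dim(frame_rgb), dim(gains)))
    stop("frame and gains shapes differ")
  if (min(gains) <= 0) stop("gains must be positive")
  frame_rgb * gains
}

#' Global diagonal gains of an RGB image
#'
#' Reciprocals of the global spatial means per channel; applying them maps
#' the image mean to (1, 1, 1).
#'
#' @param rgb_img rows x cols x 3 array.
#' @param mask Optional logical matrix restricting the spatial mean.
#' @return Length-3 gain vector.
#' @export
global_gains <- function(rgb_img, mask = NULL) {
  g <- vapply(1:3, function(ch) {
    m <- rgb_img[, , ch]
    mu <- if (is.null(mask)) mean(m) else mean(m[mask])
    if (!is.finite(mu) || mu == 0) stop("zero global mean; cannot form gains")
    1 / mu
  }, numeric(1))
  g
}

#' Global diagonal (von Kries) correction
#'
#' One diagonal transform for every pixel, with scalars that depend only
#' on the global spatial means.
#'
#' @param frame_rgb rows x cols x 3 array.
#' @param gains Length-3 gain vector (see [global_gains()]).
#' @return Corrected rows x cols x 3 array.
#' @export
diagonal_correct_global <- function(frame_rgb, gains) {
  if (length(gains) != 3 || any(!is.finite(gains)) || any(gains <= 0))
    stop("gains must be three positive scalars")
  out <- frame_rgb
  for (ch in 1:3) out[, , ch] <- frame_rgb[, , ch] * gains[ch]
  out
}

#' Median CAM16-UCS color difference between two RGB images
#'
#' Maps both images to CAM16-UCS (skipping the CAT16 stage, see
#' [cam16_ucs_coords()]), takes the per-pixel Euclidean color difference
#' and returns its median (robust to outlier pixels).
#'
#' @param local_img,global_img rows x cols x 3 cone-like RGB arrays.
#' @param vc A [viewing_conditions()] object.
#' @param mask Optional logical matrix (e.g., the 5-degree disc).
#' @return Scalar median color difference.
#' @export
median_delta_e <- function(local_img, global_img, vc = viewing_conditions(),
                           mask = NULL) {
  if (!identical(dim(local_img), dim(global_img)))
    stop("image shapes differ")
  de <- delta_e_ucs(cam16_ucs_coords(local_img, vc),
                    cam16_ucs_coords(global_img, vc))
  if (!is.null(mask)) de <- de[mask]
  stats::median(de)
}

#' Logarithmically spaced evaluation frames
#'
#' Geometrically spaced frame indices from `first_index` to
#' `n_frames - 1`, rounded to integers and deduplicated (the adaptation
#' estimate at frame n corrects the frame at n + 1, hence the last
#' evaluation sits one frame before the end).
#'
#' @param n_frames Total frame count (default 15000).
#' @param count Number of evaluation times (default 6).
#' @param first_index First evaluation frame (default 3).
#' @return Integer vector of frame indices.
#' @export
evaluation_times <- function(n_frames = 15000, count = 6, first_index = 3) {
  if (count < 2) stop("count must be >= 2")
  last <- n_frames - 1
  if (first_index < 1 || first_index >= last)
    stop("first_index out of range")
  if (count > last - first_index + 1)
    stop("count exceeds the available index range")
  idx <- unique(as.integer(round(exp(seq(log(first_index), log(last),
                                         length.out = count)))))
  idx
}

#' Time course of local-versus-global adaptation under an illuminant change
#'
#' Relights an effective-reflectance scene with a daylight illuminant of
#' the given correlated color temperature, then, at each evaluation frame
#' n: estimates the local adaptation state from the exponentially weighted
#' history of eccentricity-blurred retinal images (in CAM16 RGB) at the
#' gaze positions up to t_n, corrects the retinal image at t_(n+1) both
#' locally (per-pixel reciprocal gains) and globally (reciprocal global
#' spatial means), and records the median CAM16-UCS color difference
#' between the two corrections over the 5-degree disc.
#'
#' The weighted history is accumulated recursively (the exponential kernel
#' makes the weighted sum a one-pass recursion), so each frame is visited
#' once regardless of the number of evaluation times. Samples marked
#' invalid contribute no history but time still elapses over them.
#'
#' @param scene_reflectance A reflectance `spectral_image` at analysis
#'   resolution.
#' @param trace A `gaze_trace` covering the scene.
#' @param illuminant_cct CCT (K) of the introduced global illuminant
#'   (default 4000).
#' @param tau_s Adaptation time constant (s); 1 and 10 are the study
#'   values.
#' @param vc Viewing conditions for the color difference (default:
#'   neutral white, since corrected images have mean near (1, 1, 1)).
#' @param count,first_index Evaluation grid, see [evaluation_times()].
#' @param profile,sigma0_px,sigma_cap_px Retinal sampling parameters, see
#'   [make_retinal_frame()].
#' @param eps_frac Gain floor fraction.
#' @param jnd Reference just-noticeable difference carried in the result.
#' @param meta Optional labels.
#' @return Object of class `"adaptation_course"`: evaluation `indices`,
#'   `times_s`, `median_dE`, `tau_s`, `jnd`, `meta`.
#' @export
adaptation_timecourse <- function(scene_reflectance, trace,
                                  illuminant_cct = 4000, tau_s = 1,
                                  vc = viewing_conditions(),
                                  count = 6, first_index = 3,
                                  profile = default_density_profile(),
                                  sigma0_px = 1.0, sigma_cap_px = 8,
                                  eps_frac = 1e-6, jnd = 2.46,
                                  meta = list()) {
  stopifnot(inherits(scene_reflectance, "spectral_image"),
            inherits(trace, "gaze_trace"))
  n <- length(trace$times_s)
  idx <- evaluation_times(n, count, first_index)
  relit <- apply_illuminant(scene_reflectance,
                            daylight_spd(illuminant_cct))
  rgb_img <- xyz_to_cam16_rgb(cube_to_xyz(relit))
  gg <- global_gains(rgb_img)
  dpp <- relit$degrees_per_pixel
  h <- dim(rgb_img)[1]; w <- dim(rgb_img)[2]
  sampler <- .retinal_sampler(list(rgb_img[, , 1], rgb_img[, , 2],
                                   rgb_img[, , 3]),
                              dpp, profile, sigma0_px,
                              sigma_cap_px = sigma_cap_px)
  px <- .gaze_pixel(trace$x_deg, trace$y_deg, dpp, h, w)
  dt <- .trace_interval(trace)
  decay <- exp(-dt / tau_s)
  nl <- length(sampler$levels)
  psz <- 2 * sampler$r + 1
  acc <- lapply(seq_len(nl), function(l)
    lapply(1:3, function(ch) matrix(0, psz, psz)))
  wsum <- 0
  med <- numeric(length(idx))
  times <- numeric(length(idx))
  ei <- 1L
  for (k in seq_len(max(idx) + 1L)) {
    if (k > 1) {
      for (l in seq_len(nl)) for (ch in 1:3)
        acc[[l]][[ch]] <- acc[[l]][[ch]] * decay
      wsum <- wsum * decay
    }
    if (ei <= length(idx) && k == idx[ei] + 1L) {
      # adaptation state from the history f_1..f_(k-1); the decay step
      # above advanced all weights to time t_k, which rescales them
      # equally and cancels in the normalization
      if (wsum <= 0) stop("no valid history frames before evaluation time")
      state <- .blend_levels(acc, sampler)
      state <- state / wsum
      gains <- .reciprocal_gains(state, eps_frac)
      frame <- .sampler_patch(sampler, px[k, 1], px[k, 2])
      frame <- array(c(frame[[1]], frame[[2]], frame[[3]]),
                     c(psz, psz, 3))
      local_c <- diagonal_correct_local(frame, gains)
      global_c <- diagonal_correct_global(frame, gg)
      med[ei] <- median_delta_e(local_c, global_c, vc, mask = sampler$mask)
      times[ei] <- trace$times_s[k]
      ei <- ei + 1L
    }
    if (trace$valid[k]) {
      rows <- (px[k, 1] + sampler$pad - sampler$r):
        (px[k, 1] + sampler$pad + sampler$r)
      cols <- (px[k, 2] + sampler$pad - sampler$r):
        (px[k, 2] + sampler$pad + sampler$r)
      for (l in seq_len(nl)) for (ch in 1:3)
        acc[[l]][[ch]] <- acc[[l]][[ch]] +
          sampler$blurred[[l]][[ch]][rows, cols]
      wsum <- wsum + 1
    }
  }
  structure(list(indices = idx, times_s = times, median_dE = med,
                 tau_s = tau_s, illuminant_cct = illuminant_cct,
                 jnd = jnd, meta = meta),
            class = "adaptation_course")
}

# blend per-level accumulators into one rows x cols x 3 array using the
# sampler's per-pixel level weights
.blend_levels <- function(acc, s) {
  nl <- length(s$levels)
  psz <- 2 * s$r + 1
  out <- array(0, c(psz, psz, 3))
  for (ch in 1:3) {
    if (nl == 1) {
      out[, , ch] <- acc[[1]][[ch]]
    } else {
      m <- matrix(0, psz, psz)
      for (l in seq_len(nl)) {
        wl <- ifelse(s$lo == l, s$wlo, 0) + ifelse(s$hi == l, 1 - s$wlo, 0)
        wl[s$lo == l & s$hi == l] <- 1
        if (any(wl > 0)) m <- m + wl * acc[[l]][[ch]]
      }
      out[, , ch] <- m
    }
  }
  out
}

#' @export
print.adaptation_course <- function(x, ...) {
  cat(sprintf("<adaptation_course> tau = %g s, illuminant %g K\n",
              x$tau_s, x$illuminant_cct))
  df <- data.frame(frame = x$indices, time_s = signif(x$times_s, 4),
                   median_dE = signif(x$median_dE, 4))
  print(df, row.names = FALSE)
  cat(sprintf("reference jnd: %g (min dE = %.3g = %.2g jnd)\n",
              x$jnd, min(x$median_dE), min(x$median_dE) / x$jnd))
  invisible(x)
}

#' @export
plot.adaptation_course <- function(x, ...) {
  graphics::plot(x$times_s, x$median_dE, log = "x", type = "b", pch = 16,
                 xlab = "time from gaze onset (s)",
                 ylab = "median CAM16-UCS color difference", ...)
  graphics::abline(h = x$jnd * seq_len(ceiling(max(x$median_dE) / x$jnd)),
                   lty = 3, col = "gray")
  invisible(x)
}

#' Median color difference of an uncorrected illuminant change
#'
#' The impact of introducing a global test illuminant with no adaptation
#' correction at all: the scene is rendered under the original illuminant
#' and under a daylight illuminant of `test_cct`, both mapped to CAM16-UCS
#' with the same viewing conditions, and the median per-pixel color
#' difference is returned.
#'
#' @param scene_reflectance A reflectance `spectral_image`.
#' @param original_illuminant A `spectrum` (the scene's own illumination).
#' @param test_cct CCT (K) of the introduced daylight illuminant.
#' @param vc Viewing conditions; by default the white is the cone-like RGB
#'   of the original illuminant.
#' @return Scalar median color difference.
#' @export
uncorrected_delta_e <- function(scene_reflectance, original_illuminant,
                                test_cct = 4000, vc = NULL) {
  stopifnot(inherits(scene_reflectance, "spectral_image"))
  r1 <- apply_illuminant(scene_reflectance, original_illuminant)
  r2 <- apply_illuminant(scene_reflectance, daylight_spd(test_cct))
  rgb1 <- xyz_to_cam16_rgb(cube_to_xyz(r1))
  rgb2 <- xyz_to_cam16_rgb(cube_to_xyz(r2))
  if (is.null(vc)) {
    wh <- xyz_to_cam16_rgb(spd_to_xyz(resample_spectrum(
      original_illuminant, scene_reflectance$wavelengths_nm)))
    vc <- viewing_conditions(white_rgb = wh)
  }
  median_delta_e(rgb1, rgb2, vc)
}
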
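#' Relative cone-density profile
#'
#' Smooth stand-in for foveal cone-density falloff: d(e)/d(0) =
#' (1 + e/e_half)^-2, an inverse-square decline with eccentricity e in
#' degrees. The retinal blur scales as the reciprocal of this density.
#' Any function mapping eccentricity (deg) to relative density in (0, 1]
#' with d(0) = 1 can be used in its place, e.g. one built from a tabulated
#' profile via [density_profile_from_csv()].
#'
#' @param e_half Eccentricity scale (deg) at which density falls to 1/4.
#' @return A function of eccentricity.
#' @export
default_density_profile <- function(e_half = 1.0) {
  force(e_half)
  function(e) (1 + e / e_half)^-2
}

#' @rdname default_density_profile
#' @param path CSV with columns `eccentricity_deg,relative_density`.
#' @export
density_profile_from_csv <- function(path) {
  tbl <- utils::read.csv(path)
  if (!all(c("eccentricity_deg", "relative_density") %in% names(tbl)))
    stop("profile CSV needs columns eccentricity_deg,relative_density")
  function(e) stats::approx(tbl$eccentricity_deg, tbl$relative_density,
                            xout = e, rule = 2)$y
}

#' Mirror-pad a cone image
#'
#' Reflection padding ("the image padded with its own mirror image") on
#' all four borders, so every gaze position inside the original image
#' yields a full, equally sized retinal patch. Pads larger than the image
#' repeat the reflection (tiling) with a warning.
#'
#' @param image A `cone_image`.
#' @param pad_deg Padding width in degrees (at least the patch radius).
#' @return The padded `cone_image`.
#' @export
mirror_pad <- function(image, pad_deg) {
  stopifnot(inherits(image, "cone_image"))
  pad <- as.integer(ceiling(pad_deg / image$degrees_per_pixel))
  if (pad > min(dim(image$qL)))
    warning("padding exceeds the image size; reflection repeats")
  cone_image(.reflect_pad_matrix(image$qL, pad, pad, pad, pad),
             .reflect_pad_matrix(image$qM, pad, pad, pad, pad),
             .reflect_pad_matrix(image$qS, pad, pad, pad, pad),
             degrees_per_pixel = image$degrees_per_pixel)
}

# Row-normalized truncated-Gaussian convolution operator of length n:
# band matrix with |i-j| <= ceiling(4*sigma), each row renormalized to
# sum 1, so DC gain is exactly 1 at every position including edges.
.gauss_op <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(4 * sigma)
  idx <- seq_len(n)
  k <- outer(idx, idx, function(i, j) {
    d <- abs(i - j)
    ifelse(d <= r, exp(-d^2 / (2 * sigma^2)), 0)
  })
  k / rowSums(k)
}

#' Fixed-sigma Gaussian blur of a matrix
#'
#' Separable Gaussian blur with truncated support (4 sigma) and per-pixel
#' kernel renormalization, giving exactly unit DC gain everywhere.
#'
#' @param m Numeric matrix.
#' @param sigma Standard deviation in pixels; 0 returns `m` unchanged.
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  .gauss_op(nrow(m), sigma) %*% m %*% t(.gauss_op(ncol(m), sigma))
}

# Retinal sampler: precomputed machinery for extracting eccentricity-
# blurred 5-degree patches of a 3-channel field at arbitrary gaze
# positions. The spatially varying blur is realised by blurring the
# mirror-padded field at a small set of sigma levels and blending levels
# per patch pixel, linearly in sigma; the center pixel sits exactly on the
# sigma0 level.
.retinal_sampler <- function(fields, degrees_per_pixel,
                             profile = default_density_profile(),
                             sigma0_px = 1.0, patch_radius_deg = 2.5,
                             sigma_cap_px = 8, n_levels = 6) {
  dpp <- degrees_per_pixel
  r <- as.integer(round(patch_radius_deg / dpp))
  h <- nrow(fields[[1]]); w <- ncol(fields[[1]])
  # eccentricity and sigma over the patch grid
  off <- seq(-r, r)
  ecc <- sqrt(outer(off^2, off^2, "+")) * dpp
  d0 <- profile(0)
  sig <- sigma0_px * d0 / profile(ecc)
  if (any(sig < sigma0_px - 1e-9))
    stop("density profile must not exceed its foveal value")
  sig <- pmin(sig, sigma_cap_px)
  smax <- max(sig)
  levels <- if (smax - sigma0_px < 1e-9) sigma0_px
            else unique(exp(seq(log(sigma0_px), log(smax),
                                length.out = n_levels)))
  pad <- r + as.integer(ceiling(4 * max(levels)))
  padded <- lapply(fields, .reflect_pad_matrix, pad, pad, pad, pad)
  blurred <- lapply(levels, function(s) lapply(padded, gaussian_blur, s))
  # per-pixel level bracket and interpolation weight
  li <- findInterval(sig, levels, rightmost.closed = TRUE)
  li[li < 1] <- 1
  hi <- pmin(li + 1, length(levels))
  denom <- levels[hi] - levels[li]
  wlo <- ifelse(denom > 0, (levels[hi] - sig) / denom, 1)
  mask <- ecc <= patch_radius_deg + 1e-12
  list(levels = levels, blurred = blurred, pad = pad, r = r, dpp = dpp,
       h = h, w = w, lo = li, hi = hi, wlo = wlo, mask = mask, ecc = ecc,
       sigma = sig)
}

.gaze_pixel <- function(x_deg, y_deg, dpp, h, w) {
  col <- pmin(pmax(round(x_deg / dpp + 0.5), 1), w)
  row <- pmin(pmax(round(y_deg / dpp + 0.5), 1), h)
  cbind(row, col)
}

# Extract the blended patch (list of channel matrices) at a gaze pixel.
.sampler_patch <- function(s, row, col) {
  rows <- (row + s$pad - s$r):(row + s$pad + s$r)
  cols <- (col + s$pad - s$r):(col + s$pad + s$r)
  nl <- length(s$levels)
  lapply(seq_along(s$blurred[[1]]), function(ch) {
    if (nl == 1) return(s$blurred[[1]][[ch]][rows, cols])
    acc <- matrix(0, length(rows), length(cols))
    for (l in seq_len(nl)) {
      wl <- ifelse(s$lo == l, s$wlo, 0) + ifelse(s$hi == l, 1 - s$wlo, 0)
      wl[s$lo == l & s$hi == l] <- 1
      if (any(wl > 0)) acc <- acc + wl * s$blurred[[l]][[ch]][rows, cols]
    }
    acc
  })
}

#' Eccentricity-blurred retinal frame at a gaze position
#'
#' Extracts the 5-degree-diameter cone-excitation patch centered on the
#' gaze position from the mirror-padded image and applies the
#' eccentricity-dependent Gaussian blur: standard deviation `sigma0_px`
#' (about 1 arcmin) at the patch center, growing as the reciprocal of the
#' relative cone density, capped at `sigma_cap_px`. Every kernel is
#' normalized, so blur preserves constants exactly. The foveal sample is
#' the blurred value at the center pixel.
#'
#' @param image A `cone_image`.
#' @param gaze `c(x_deg, y_deg)` inside the image bounds.
#' @param profile Relative cone-density function of eccentricity (deg).
#' @param sigma0_px Foveal blur standard deviation in pixels.
#' @param patch_radius_deg Patch radius (deg), default 2.5.
#' @param sigma_cap_px Cap on the blur sigma at the patch rim.
#' @param time_s Optional timestamp carried on the frame.
#' @return Object of class `"retinal_frame"`: blurred `qL`, `qM`, `qS`
#'   patch matrices, logical disc `mask`, `fovea` cone triple, `gaze`,
#'   `time_s` and `degrees_per_pixel`.
#' @export
make_retinal_frame <- function(image, gaze,
                               profile = default_density_profile(),
                               sigma0_px = 1.0, patch_radius_deg = 2.5,
                               sigma_cap_px = 8, time_s = NA_real_) {
  stopifnot(inherits(image, "cone_image"))
  dpp <- image$degrees_per_pixel
  h <- nrow(image$qL); w <- ncol(image$qL)
  if (gaze[1] < 0 || gaze[1] > w * dpp || gaze[2] < 0 || gaze[2] > h * dpp)
    stop("gaze position outside the image bounds")
  s <- .retinal_sampler(list(image$qL, image$qM, image$qS), dpp, profile,
                        sigma0_px, patch_radius_deg, sigma_cap_px)
  px <- .gaze_pixel(gaze[1], gaze[2], dpp, h, w)
  patch <- .sampler_patch(s, px[1, 1], px[1, 2])
  ctr <- s$r + 1
  fovea <- c(qL = patch[[1]][ctr, ctr], qM = patch[[2]][ctr, ctr],
             qS = patch[[3]][ctr, ctr])
  structure(list(qL = patch[[1]], qM = patch[[2]], qS = patch[[3]],
                 mask = s$mask, fovea = fovea, gaze = as.numeric(gaze),
                 time_s = time_s, degrees_per_pixel = dpp),
            class = "retinal_frame")
}

#' @export
print.retinal_frame <- function(x, ...) {
  cat(sprintf("<retinal_frame> %d x %d px patch, gaze (%.3g, %.3g) deg\n",
              nrow(x$qL), ncol(x$qL), x$gaze[1], x$gaze[2]))
  invisible(x)
}

#' Foveal cone-excitation time series
#'
#' The sequence of foveal-center cone triples along a gaze trace: for each
#' valid sample, the sigma0-blurred cone excitation at the gaze pixel
#' (identical to the center of [make_retinal_frame()], computed without
#' building full patches). Invalid samples are omitted.
#'
#' @param image A `cone_image`.
#' @param trace A `gaze_trace` (filter it first with [filter_speed()]).
#' @param profile Cone-density profile (only its foveal value matters
#'   here; kept for interface symmetry).
#' @param sigma0_px Foveal blur sigma in pixels.
#' @return A numeric matrix (n_valid x 3, columns qL, qM, qS) of class
#'   `"cone_series"` with the sample times as attribute `times_s`.
#' @export
foveal_series <- function(image, trace,
                          profile = default_density_profile(),
                          sigma0_px = 1.0) {
  stopifnot(inherits(image, "cone_image"), inherits(trace, "gaze_trace"))
  keep <- trace$valid
  if (!any(keep)) stop("no valid samples in the gaze trace")
  h <- nrow(image$qL); w <- ncol(image$qL)
  dpp <- image$degrees_per_pixel
  x <- trace$x_deg[keep]; y <- trace$y_deg[keep]
  if (any(x < 0 | x > w * dpp | y < 0 | y > h * dpp))
    stop("gaze positions outside the image bounds")
  pad <- as.integer(ceiling(4 * sigma0_px))
  bl <- lapply(list(image$qL, image$qM, image$qS), function(m)
    gaussian_blur(.reflect_pad_matrix(m, pad, pad, pad, pad), sigma0_px))
  px <- .gaze_pixel(x, y, dpp, h, w)
  idx <- cbind(px[, 1] + pad, px[, 2] + pad)
  out <- cbind(qL = bl[[1]][idx], qM = bl[[2]][idx], qS = bl[[3]][idx])
  attr(out, "times_s") <- trace$times_s[keep]
  class(out) <- c("cone_series", class(out))
  out
}
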
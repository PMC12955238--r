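#' The CAM16 XYZ-to-RGB matrix
#'
#' Fixed 3x3 matrix mapping CIE 1931 tristimulus values to the cone-like
#' R, G, B responses of CAM16 (column-vector convention,
#' RGB = M16 %*% XYZ).
#'
#' @return 3x3 numeric matrix.
#' @export
m16_matrix <- function() {
  matrix(c(0.401288, 0.650173, -0.051461,
           -0.250268, 1.204414, 0.045854,
           -0.002079, 0.048952, 0.953127),
         nrow = 3, byrow = TRUE)
}

#' CAM16 cone-like responses from tristimulus values
#'
#' Applies the M16 matrix. Accepts a length-3 vector, an N x 3 matrix, or
#' a height x width x 3 array; the shape is preserved.
#'
#' @param xyz Tristimulus values.
#' @return Cone-like R, G, B responses in the same shape.
#' @export
xyz_to_cam16_rgb <- function(xyz) {
  m <- m16_matrix()
  if (is.array(xyz) && length(dim(xyz)) == 3) {
    d <- dim(xyz)
    out <- matrix(xyz, d[1] * d[2], 3) %*% t(m)
    return(array(out, d))
  }
  if (is.matrix(xyz)) return(xyz %*% t(m))
  v <- as.numeric(m %*% xyz)
  names(v) <- c("R", "G", "B")
  v
}

#' CAM16 viewing conditions
#'
#' Parameters of the CAM16 post-adaptation stages. The chromatic
#' adaptation transform (CAT16) is never run by this package -- adaptation
#' is modelled explicitly by the diagonal corrections -- so the reference
#' white is specified directly in cone-like RGB. Corrected images have
#' their global mean mapped to (1, 1, 1), hence the neutral default.
#'
#' @param white_rgb Cone-like RGB of the reference white (post-correction
#'   scale; default neutral (1,1,1)).
#' @param adapting_luminance Adapting field luminance L_A in cd/m^2.
#' @param background_relative_luminance Background relative luminance Y_b
#'   (percent of white, in (0, 100]).
#' @param surround One of "average", "dim", "dark".
#' @return Object of class `"viewing_conditions"` with derived constants.
#' @export
viewing_conditions <- function(white_rgb = c(1, 1, 1),
                               adapting_luminance = 20,
                               background_relative_luminance = 20,
                               surround = c("average", "dim", "dark")) {
  surround <- match.arg(surround)
  if (!is.numeric(white_rgb) || length(white_rgb) != 3 ||
      any(!is.finite(white_rgb)) || any(white_rgb <= 0))
    stop("white_rgb must be three positive finite values")
  if (!is.finite(adapting_luminance) || adapting_luminance <= 0)
    stop("adapting_luminance must be > 0")
  yb <- background_relative_luminance
  if (!is.finite(yb) || yb <= 0 || yb > 100)
    stop("background_relative_luminance must be in (0, 100]")
  sp <- switch(surround,
               average = c(F = 1.0, c = 0.69, Nc = 1.0),
               dim = c(F = 0.9, c = 0.59, Nc = 0.9),
               dark = c(F = 0.8, c = 0.525, Nc = 0.8))
  la <- adapting_luminance
  k <- 1 / (5 * la + 1)
  fl <- 0.2 * k^4 * 5 * la + 0.1 * (1 - k^4)^2 * (5 * la)^(1 / 3)
  n <- yb / 100
  nbb <- 0.725 * n^-0.2
  z <- 1.48 + sqrt(n)
  # The stimulus scale is set so the reference white maps to 100
  # (achromatic scaling only; never a per-channel gain).
  scale <- 100 / mean(white_rgb)
  wa <- .cam16_compress(white_rgb * scale, fl)
  aw <- (2 * wa[1] + wa[2] + wa[3] / 20 - 0.305) * nbb
  structure(list(white_rgb = white_rgb, adapting_luminance = la,
                 background_relative_luminance = yb, surround = surround,
                 F = sp[["F"]], c = sp[["c"]], Nc = sp[["Nc"]],
                 FL = fl, n = n, Nbb = nbb, Ncb = nbb, z = z,
                 scale = scale, Aw = aw),
            class = "viewing_conditions")
}

# CAM16 post-adaptation nonlinear response compression (signed).
.cam16_compress <- function(rgb, fl) {
  x <- fl * rgb / 100
  ax <- abs(x)^0.42
  sign(x) * 400 * ax / (ax + 27.13) + 0.1
}

#' CAM16-UCS coordinates of cone-like responses
#'
#' Runs the CAM16 post-adaptation stages (response compression, opponent
#' signals, lightness J, colorfulness M, hue angle h) directly on the
#' supplied cone-like RGB -- the CAT16 chromatic adaptation step is
#' deliberately skipped, since adaptation is modelled explicitly by the
#' diagonal corrections -- and then applies the CAM16-UCS transform
#' J' = 1.7 J / (1 + 0.007 J), M' = ln(1 + 0.0228 M) / 0.0228,
#' a' = M' cos h, b' = M' sin h.
#'
#' @param rgb Length-3 vector, N x 3 matrix, or height x width x 3 array
#'   of cone-like responses (same scale as `vc$white_rgb`).
#' @param vc A [viewing_conditions()] object.
#' @return Same shape as the input with components (J', a', b'); for a
#'   vector input a named length-3 vector.
#' @export
cam16_ucs_coords <- function(rgb, vc = viewing_conditions()) {
  stopifnot(inherits(vc, "viewing_conditions"))
  shape <- NULL
  if (is.array(rgb) && length(dim(rgb)) == 3) {
    shape <- dim(rgb)
    rgb <- matrix(rgb, shape[1] * shape[2], 3)
  } else if (!is.matrix(rgb)) {
    rgb <- matrix(rgb, 1, 3)
    shape <- "vector"
  }
  a_ <- .cam16_compress(rgb * vc$scale, vc$FL)
  ra <- a_[, 1]; ga <- a_[, 2]; ba <- a_[, 3]
  a <- ra - 12 * ga / 11 + ba / 11
  b <- (ra + ga - 2 * ba) / 9
  h <- atan2(b, a)
  achr <- (2 * ra + ga + ba / 20 - 0.305) * vc$Nbb
  achr <- pmax(achr, 0)
  j <- 100 * (achr / vc$Aw)^(vc$c * vc$z)
  et <- 0.25 * (cos(h + 2) + 3.8)
  t <- (50000 / 13) * vc$Nc * vc$Ncb * et * sqrt(a^2 + b^2) /
    (ra + ga + 21 * ba / 20)
  t <- pmax(t, 0)
  cc <- t^0.9 * sqrt(j / 100) * (1.64 - 0.29^vc$n)^0.73
  m <- cc * vc$FL^0.25
  jp <- 1.7 * j / (1 + 0.007 * j)
  mp <- log1p(0.0228 * m) / 0.0228
  out <- cbind(jp, mp * cos(h), mp * sin(h))
  colnames(out) <- c("Jp", "ap", "bp")
  if (identical(shape, "vector")) {
    v <- out[1, ]
    names(v) <- c("Jp", "ap", "bp")
    return(v)
  }
  if (!is.null(shape)) return(array(out, shape))
  out
}

#' CAM16-UCS color difference
#'
#' Euclidean distance in (J', a', b').
#'
#' @param p,q UCS coordinates: length-3 vectors, N x 3 matrices, or
#'   height x width x 3 arrays of matching shape.
#' @return Scalar, vector, or matrix of distances.
#' @export
delta_e_ucs <- function(p, q) {
  if (is.array(p) && length(dim(p)) == 3) {
    d <- (p - q)^2
    return(sqrt(d[, , 1] + d[, , 2] + d[, , 3]))
  }
  if (is.matrix(p)) return(sqrt(rowSums((p - q)^2)))
  sqrt(sum((p - q)^2))
}

#' CAM16 appearance correlates (J, M, h) without the adaptation transform
#'
#' Mostly a validation surface: given post-adaptation cone-like responses
#' (i.e., already chromatically adapted RGB on the 0--100 scale used by
#' the CAM16 reference formulation), returns lightness J, colorfulness M
#' and hue angle h in degrees.
#'
#' @param rgb_adapted Length-3 adapted RGB (reference-white scale 0--100).
#' @param white_adapted Adapted RGB of the reference white on that scale.
#' @param adapting_luminance,background_relative_luminance,surround As in
#'   [viewing_conditions()].
#' @return Named vector c(J, M, h).
#' @export
cam16_jmh <- function(rgb_adapted, white_adapted,
                      adapting_luminance = 20,
                      background_relative_luminance = 20,
                      surround = "average") {
  sp <- switch(surround,
               average = c(F = 1.0, c = 0.69, Nc = 1.0),
               dim = c(F = 0.9, c = 0.59, Nc = 0.9),
               dark = c(F = 0.8, c = 0.525, Nc = 0.8))
  la <- adapting_luminance
  k <- 1 / (5 * la + 1)
  fl <- 0.2 * k^4 * 5 * la + 0.1 * (1 - k^4)^2 * (5 * la)^(1 / 3)
  n <- background_relative_luminance / 100
  nbb <- 0.725 * n^-0.2
  z <- 1.48 + sqrt(n)
  vc <- list(FL = fl, n = n, Nbb = nbb, Ncb = nbb, z = z,
             c = sp[["c"]], Nc = sp[["Nc"]])
  wa <- .cam16_compress(white_adapted, fl)
  vc$Aw <- (2 * wa[1] + wa[2] + wa[3] / 20 - 0.305) * nbb
  a_ <- .cam16_compress(rgb_adapted, fl)
  ra <- a_[1]; ga <- a_[2]; ba <- a_[3]
  a <- ra - 12 * ga / 11 + ba / 11
  b <- (ra + ga - 2 * ba) / 9
  h <- atan2(b, a)
  hdeg <- (h * 180 / pi) %% 360
  achr <- (2 * ra + ga + ba / 20 - 0.305) * vc$Nbb
  j <- 100 * (max(achr, 0) / vc$Aw)^(vc$c * vc$z)
  et <- 0.25 * (cos(h + 2) + 3.8)
  t <- (50000 / 13) * vc$Nc * vc$Ncb * et * sqrt(a^2 + b^2) /
    (ra + ga + 21 * ba / 20)
  cc <- t^0.9 * sqrt(j / 100) * (1.64 - 0.29^vc$n)^0.73
  c(J = j, M = cc * vc$FL^0.25, h = hdeg)
}
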
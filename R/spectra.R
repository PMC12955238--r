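.gd_cache <- new.env(parent = emptyenv())

#' Canonical wavelength grid
#'
#' The analysis grid used throughout the package: 400--720 nm in 10 nm
#' steps (33 bands). All spectral inputs are linearly resampled onto it.
#'
#' @return Numeric vector of wavelengths in nm.
#' @export
canonical_grid <- function() seq(400, 720, by = 10)

#' Spectrum constructor
#'
#' A sampled spectral power distribution (radiance or relative power) on a
#' strictly increasing wavelength grid.
#'
#' @param wavelengths_nm Strictly increasing numeric grid (nm).
#' @param values Nonnegative finite values, one per wavelength.
#' @return An object of class `"spectrum"`.
#' @export
spectrum <- function(wavelengths_nm, values) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values))
    stop("wavelengths and values must have the same length")
  if (any(!is.finite(wavelengths_nm)) || any(diff(wavelengths_nm) <= 0))
    stop("wavelength grid must be finite and strictly increasing")
  if (any(!is.finite(values)))
    stop("spectrum values must be finite")
  if (any(values < 0))
    stop("spectrum values must be nonnegative")
  structure(list(wavelengths_nm = wavelengths_nm, values = values),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d bands, %g-%g nm, max %.4g\n",
              length(x$values), min(x$wavelengths_nm),
              max(x$wavelengths_nm), max(x$values)))
  invisible(x)
}

#' Resample a spectrum onto a target grid
#'
#' Linear interpolation; outside the source range the end values are held
#' constant (spectra here are smooth and the canonical grid is interior to
#' all shipped tables).
#'
#' @param x A `spectrum`.
#' @param grid Target wavelength grid (nm).
#' @return A `spectrum` on `grid`.
#' @export
resample_spectrum <- function(x, grid = canonical_grid()) {
  stopifnot(inherits(x, "spectrum"))
  if (length(x$wavelengths_nm) == length(grid) &&
      all(x$wavelengths_nm == grid)) return(x)
  v <- stats::approx(x$wavelengths_nm, x$values, xout = grid, rule = 2)$y
  spectrum(grid, pmax(v, 0))
}

.read_table <- function(file) {
  key <- paste0("tbl_", file)
  if (!is.null(.gd_cache[[key]])) return(.gd_cache[[key]])
  path <- system.file("extdata", file, package = "gazediet")
  if (!nzchar(path)) stop("missing package table: ", file)
  tbl <- utils::read.csv(path)
  .gd_cache[[key]] <- tbl
  tbl
}

.resample_cols <- function(tbl, cols, grid) {
  out <- sapply(cols, function(cn)
    stats::approx(tbl$wavelength_nm, tbl[[cn]], xout = grid, rule = 2)$y)
  colnames(out) <- cols
  out
}

#' Cone fundamentals
#'
#' Loads L, M, S cone spectral sensitivities (corneal, energy units, unit
#' peak) resampled to the analysis grid. The table shipped with the package
#' is derived from the CIE 1931 2-degree color-matching functions by the
#' Hunt-Pointer-Estevez transform; a CSV with columns
#' `wavelength_nm,sL,sM,sS` (for example a Stockman-Sharpe 2-degree
#' tabulation) can be supplied via `path` instead.
#'
#' @param grid Target wavelength grid.
#' @param path Optional CSV path overriding the shipped table.
#' @return Object of class `"cone_fundamentals"`: list with
#'   `wavelengths_nm` and an `s` matrix (bands x 3, columns L, M, S).
#' @export
cone_fundamentals <- function(grid = canonical_grid(), path = NULL) {
  tbl <- if (is.null(path)) .read_table("cone_fundamentals_2deg.csv")
         else utils::read.csv(path)
  need <- c("wavelength_nm", "sL", "sM", "sS")
  if (!all(need %in% names(tbl)))
    stop("fundamentals CSV must have columns wavelength_nm,sL,sM,sS")
  s <- .resample_cols(tbl, c("sL", "sM", "sS"), grid)
  if (any(s < 0)) stop("cone sensitivities must be nonnegative")
  structure(list(wavelengths_nm = grid, s = s), class = "cone_fundamentals")
}

#' CIE 1931 2-degree color-matching functions
#'
#' @param grid Target wavelength grid.
#' @return bands x 3 matrix with columns xbar, ybar, zbar.
#' @export
cie_cmf <- function(grid = canonical_grid()) {
  .resample_cols(.read_table("cie1931_cmf_2deg_10nm.csv"),
                 c("xbar", "ybar", "zbar"), grid)
}

.grid_step <- function(grid) {
  d <- diff(grid)
  if (max(d) - min(d) > 1e-9) stop("wavelength grid must be uniform")
  d[1]
}

#' Cone excitations from a spectrum or spectral image
#'
#' Numerically integrates radiance against the cone fundamentals,
#' q = sum over wavelength of L(lambda) S(lambda) d(lambda), on the common
#' analysis grid (10 nm steps by default).
#'
#' @param x A `spectrum` or a `spectral_image`.
#' @param fundamentals A `cone_fundamentals` object; resampled to `x`'s
#'   grid if necessary.
#' @return For a spectrum, a named numeric vector `c(qL, qM, qS)`; for a
#'   spectral image, a `cone_image`.
#' @export
cone_excitations <- function(x, fundamentals = cone_fundamentals()) {
  UseMethod("cone_excitations")
}

.match_fundamentals <- function(fundamentals, grid) {
  if (length(fundamentals$wavelengths_nm) == length(grid) &&
      all(fundamentals$wavelengths_nm == grid)) return(fundamentals)
  tbl <- data.frame(wavelength_nm = fundamentals$wavelengths_nm,
                    sL = fundamentals$s[, 1], sM = fundamentals$s[, 2],
                    sS = fundamentals$s[, 3])
  s <- .resample_cols(tbl, c("sL", "sM", "sS"), grid)
  structure(list(wavelengths_nm = grid, s = s), class = "cone_fundamentals")
}

#' @export
cone_excitations.spectrum <- function(x, fundamentals = cone_fundamentals()) {
  f <- .match_fundamentals(fundamentals, x$wavelengths_nm)
  dl <- .grid_step(x$wavelengths_nm)
  q <- as.numeric(crossprod(f$s, x$values)) * dl
  names(q) <- c("qL", "qM", "qS")
  q
}

#' @export
cone_excitations.spectral_image <- function(x,
                                            fundamentals = cone_fundamentals()) {
  f <- .match_fundamentals(fundamentals, x$wavelengths_nm)
  dl <- .grid_step(x$wavelengths_nm)
  d <- dim(x$data)
  m <- matrix(x$data, d[1] * d[2], d[3]) %*% f$s * dl
  cone_image(qL = matrix(m[, 1], d[1], d[2]),
             qM = matrix(m[, 2], d[1], d[2]),
             qS = matrix(m[, 3], d[1], d[2]),
             degrees_per_pixel = x$degrees_per_pixel)
}

#' Cone-excitation image constructor
#'
#' @param qL,qM,qS Matrices of nonnegative excitations (same shape).
#' @param degrees_per_pixel Angular scale (deg per pixel).
#' @return Object of class `"cone_image"`.
#' @export
cone_image <- function(qL, qM, qS, degrees_per_pixel) {
  if (!all(dim(qL) == dim(qM)) || !all(dim(qL) == dim(qS)))
    stop("cone channels must share a shape")
  if (any(!is.finite(qL)) || any(!is.finite(qM)) || any(!is.finite(qS)))
    stop("cone excitations must be finite")
  if (min(qL, qM, qS) < 0) stop("cone excitations must be nonnegative")
  stopifnot(degrees_per_pixel > 0)
  structure(list(qL = qL, qM = qM, qS = qS,
                 degrees_per_pixel = degrees_per_pixel),
            class = "cone_image")
}

#' @export
print.cone_image <- function(x, ...) {
  cat(sprintf("<cone_image> %d x %d px, %.4g deg/px\n",
              nrow(x$qL), ncol(x$qL), x$degrees_per_pixel))
  invisible(x)
}

#' CIE daylight illuminant
#'
#' Reconstructs the relative spectral power distribution of a CIE daylight
#' phase of a given correlated color temperature from the daylight-locus
#' chromaticity and the S0/S1/S2 components, resampled to the analysis
#' grid. Slightly negative reconstructed values are clipped to zero, and
#' the SPD is normalized so its luminance integral (Y) equals 100.
#'
#' @param cct Correlated color temperature in kelvin, 4000--25000.
#' @param grid Target wavelength grid.
#' @return A `spectrum`.
#' @export
daylight_spd <- function(cct, grid = canonical_grid()) {
  if (!is.finite(cct) || cct < 4000 || cct > 25000)
    stop("cct must lie in [4000, 25000] K")
  t <- cct
  xd <- if (t <= 7000)
    0.244063 + 0.09911e3 / t + 2.9678e6 / t^2 - 4.6070e9 / t^3
  else
    0.237040 + 0.24748e3 / t + 1.9018e6 / t^2 - 2.0064e9 / t^3
  yd <- -3.000 * xd^2 + 2.870 * xd - 0.275
  den <- 0.0241 + 0.2562 * xd - 0.7341 * yd
  m1 <- (-1.3515 - 1.7703 * xd + 5.9114 * yd) / den
  m2 <- (0.0300 - 31.4424 * xd + 30.0717 * yd) / den
  comp <- .resample_cols(.read_table("cie_daylight_components_10nm.csv"),
                         c("S0", "S1", "S2"), grid)
  v <- comp[, "S0"] + m1 * comp[, "S1"] + m2 * comp[, "S2"]
  v <- pmax(v, 0)
  s <- spectrum(grid, v)
  y <- spd_to_xyz(s)[["Y"]]
  spectrum(grid, v * 100 / y)
}

#' Tristimulus values of a spectrum
#'
#' Integrates a spectral power distribution against the CIE 1931 2-degree
#' color-matching functions with the grid step as the quadrature weight.
#' `k` rescales the result; by convention the pipeline chooses k so a
#' perfect reflector under the scene illuminant has Y = 100 (with the
#' shipped daylight illuminants, already normalized to Y = 100, k = 1).
#'
#' @param x A `spectrum`.
#' @param k Scalar normalization constant.
#' @return Named numeric vector `c(X, Y, Z)`.
#' @export
spd_to_xyz <- function(x, k = 1) {
  stopifnot(inherits(x, "spectrum"))
  cmf <- cie_cmf(x$wavelengths_nm)
  dl <- .grid_step(x$wavelengths_nm)
  v <- as.numeric(crossprod(cmf, x$values)) * dl * k
  names(v) <- c("X", "Y", "Z")
  v
}

#' Tristimulus image of a spectral image
#'
#' @param img A `spectral_image` (radiance).
#' @param k Normalization constant, as in [spd_to_xyz()].
#' @return height x width x 3 array of X, Y, Z.
#' @export
cube_to_xyz <- function(img, k = 1) {
  stopifnot(inherits(img, "spectral_image"))
  cmf <- cie_cmf(img$wavelengths_nm)
  dl <- .grid_step(img$wavelengths_nm)
  d <- dim(img$data)
  m <- matrix(img$data, d[1] * d[2], d[3]) %*% cmf * dl * k
  array(m, c(d[1], d[2], 3))
}

#' Apply an illuminant to a reflectance image
#'
#' Pointwise per-band product of an effective reflectance cube and an
#' illuminant spectrum; the result is a radiance-kind cube.
#'
#' @param reflectance A `spectral_image` with `kind = "reflectance"`.
#' @param illuminant A `spectrum` on the same grid (resampled otherwise).
#' @return A radiance `spectral_image`.
#' @export
apply_illuminant <- function(reflectance, illuminant) {
  stopifnot(inherits(reflectance, "spectral_image"),
            inherits(illuminant, "spectrum"))
  if (reflectance$kind != "reflectance")
    stop("apply_illuminant expects a reflectance cube")
  ill <- resample_spectrum(illuminant, reflectance$wavelengths_nm)
  d <- dim(reflectance$data)
  data <- reflectance$data * rep(ill$values, each = d[1] * d[2])
  spectral_image(data, reflectance$wavelengths_nm, kind = "radiance",
                 degrees_per_pixel = reflectance$degrees_per_pixel)
}

.xyz_to_uv <- function(xyz) {
  den <- xyz[1] + 15 * xyz[2] + 3 * xyz[3]
  c(4 * xyz[1] / den, 6 * xyz[2] / den)
}

.planck_uv <- function(t, grid = canonical_grid()) {
  lam <- grid * 1e-9
  c2 <- 1.4388e-2
  v <- lam^-5 / (exp(c2 / (lam * t)) - 1)
  v <- v / max(v)
  .xyz_to_uv(spd_to_xyz(spectrum(grid, v)))
}

#' Correlated color temperature
#'
#' CCT by locus search: the Planckian temperature whose CIE 1960 (u, v)
#' chromaticity is nearest the stimulus chromaticity, refined by golden
#' section over reciprocal temperature.
#'
#' @param xyz Tristimulus values (length-3 numeric).
#' @param max_duv Maximum allowed distance from the Planckian locus in
#'   (u, v); beyond it the chromaticity has no meaningful CCT.
#' @return CCT in kelvin.
#' @export
cct_of <- function(xyz, max_duv = 0.05) {
  if (length(xyz) != 3 || any(!is.finite(xyz)) || sum(xyz) <= 0)
    stop("xyz must be three finite values with positive sum")
  uv <- .xyz_to_uv(as.numeric(xyz))
  key <- "planck_locus"
  if (is.null(.gd_cache[[key]])) {
    mired <- seq(1e6 / 30000, 1e6 / 1000, length.out = 241)
    locus <- t(vapply(1e6 / mired, .planck_uv, numeric(2)))
    .gd_cache[[key]] <- list(mired = mired, locus = locus)
  }
  pl <- .gd_cache[[key]]
  d2 <- (pl$locus[, 1] - uv[1])^2 + (pl$locus[, 2] - uv[2])^2
  i <- which.min(d2)
  lo <- pl$mired[max(1, i - 1)]
  hi <- pl$mired[min(length(pl$mired), i + 1)]
  f <- function(m) {
    p <- .planck_uv(1e6 / m)
    (p[1] - uv[1])^2 + (p[2] - uv[2])^2
  }
  opt <- stats::optimize(f, c(lo, hi), tol = 1e-4)
  if (sqrt(opt$objective) > max_duv)
    stop("chromaticity too far from the Planckian locus for a CCT")
  1e6 / opt$minimum
}

.lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

#' CIELAB chroma
#'
#' C* = sqrt(a*^2 + b*^2) under a supplied reference white.
#'
#' @param xyz Stimulus tristimulus values.
#' @param white Reference white tristimulus values (Y > 0).
#' @return Scalar chroma. `lab_of` returns the full (L*, a*, b*) triple.
#' @export
lab_chroma <- function(xyz, white) {
  lab <- lab_of(xyz, white)
  unname(sqrt(lab[2]^2 + lab[3]^2))
}

#' @rdname lab_chroma
#' @export
lab_of <- function(xyz, white) {
  if (length(white) != 3 || white[2] <= 0)
    stop("white must be a tristimulus triple with Y > 0")
  xyz <- as.numeric(xyz); white <- as.numeric(white)
  fx <- .lab_f(xyz[1] / white[1])
  fy <- .lab_f(xyz[2] / white[2])
  fz <- .lab_f(xyz[3] / white[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}
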
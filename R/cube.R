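#' Hyperspectral image constructor
#'
#' A wavelength-sampled cube (radiance or effective reflectance) with
#' angular-extent metadata.
#'
#' @param data height x width x bands array of nonnegative finite values.
#' @param wavelengths_nm Strictly increasing band grid (nm).
#' @param kind `"radiance"` or `"reflectance"`.
#' @param degrees_per_pixel Isotropic angular scale (deg per pixel).
#' @return Object of class `"spectral_image"`.
#' @export
spectral_image <- function(data, wavelengths_nm,
                           kind = c("radiance", "reflectance"),
                           degrees_per_pixel) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3) stop("data must be a 3-d array")
  if (dim(data)[3] != length(wavelengths_nm))
    stop("band count does not match the wavelength grid")
  if (any(diff(wavelengths_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(!is.finite(data))) stop("cube contains non-finite values")
  if (min(data) < 0) stop("cube values must be nonnegative")
  if (!is.finite(degrees_per_pixel) || degrees_per_pixel <= 0)
    stop("degrees_per_pixel must be positive")
  if (kind == "reflectance" && max(data) > 1 + 0.05)
    warning("reflectance cube has values well above 1")
  structure(list(data = data, wavelengths_nm = as.numeric(wavelengths_nm),
                 kind = kind, degrees_per_pixel = degrees_per_pixel),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<spectral_image> %d x %d px, %d bands (%g-%g nm), %s, %.4g deg/px\n",
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm),
              x$kind, x$degrees_per_pixel))
  invisible(x)
}

#' Write a hyperspectral cube
#'
#' The package's canonical on-disk container is an ENVI-style pair: a
#' plain-text header `<path>.hdr` and a raw little-endian binary `<path>`
#' holding 64-bit floats. Wavelengths, the radiance/reflectance flag and
#' the angular scale are carried as header fields, so a write/read round
#' trip is bit-faithful and loses no metadata.
#'
#' @param image A `spectral_image`.
#' @param path Output data-file path (header written alongside).
#' @param interleave `"bsq"`, `"bil"`, or `"bip"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(image, path, interleave = c("bsq", "bil", "bip")) {
  stopifnot(inherits(image, "spectral_image"))
  interleave <- match.arg(interleave)
  d <- dim(image$data)
  x <- image$data                      # [line, sample, band]
  perm <- switch(interleave,
                 bsq = c(2, 1, 3),     # sample fastest, then line, then band
                 bil = c(2, 3, 1),
                 bip = c(3, 2, 1))
  v <- as.numeric(aperm(x, perm))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(v, con, size = 8, endian = "little")
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           sprintf("wavelength units = nm"),
           sprintf("wavelength = { %s }",
                   paste(format(image$wavelengths_nm, trim = TRUE),
                         collapse = ", ")),
           sprintf("kind = %s", image$kind),
           sprintf("degrees per pixel = %.17g", image$degrees_per_pixel))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

.parse_envi_header <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  get1 <- function(key, required = TRUE) {
    m <- regmatches(txt, regexec(paste0("(?mi)^", key,
                                        "\\s*=\\s*([^\\n{]+)$"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) {
      if (required) stop("ENVI header missing field: ", key)
      return(NULL)
    }
    trimws(m[2])
  }
  getblock <- function(key) {
    m <- regmatches(txt, regexec(paste0("(?smi)^", key,
                                        "\\s*=\\s*\\{(.*?)\\}"),
                                 txt, perl = TRUE))[[1]]
    if (length(m) < 2) return(NULL)
    as.numeric(strsplit(m[2], "[,\\s]+")[[1]][nzchar(
      strsplit(m[2], "[,\\s]+")[[1]])])
  }
  list(samples = as.integer(get1("samples")),
       lines = as.integer(get1("lines")),
       bands = as.integer(get1("bands")),
       dtype = as.integer(get1("data type")),
       interleave = tolower(get1("interleave")),
       byte_order = as.integer(get1("byte order")),
       offset = as.integer(get1("header offset", required = FALSE) %||% "0"),
       wavelength = getblock("wavelength"),
       kind = get1("kind", required = FALSE),
       dpp = get1("degrees per pixel", required = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a hyperspectral cube
#'
#' Reads the ENVI-style container written by [write_cube()] (data types 4
#' and 5, BSQ/BIL/BIP interleaves, little- or big-endian). The header must
#' carry a wavelength block; `kind` and `degrees per pixel` default to
#' radiance and `degrees_per_pixel` when absent.
#'
#' @param path Data-file path; the header is looked up at `<path>.hdr`
#'   (or `<path sans ext>.hdr`).
#' @param degrees_per_pixel Fallback angular scale for headers without one.
#' @return A `spectral_image`.
#' @export
read_cube <- function(path, degrees_per_pixel = NULL) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path))
    hdr_path <- paste0(tools::file_path_sans_ext(path), ".hdr")
  if (!file.exists(hdr_path)) stop("no ENVI header found for ", path)
  h <- .parse_envi_header(readLines(hdr_path, warn = FALSE))
  if (is.null(h$wavelength))
    stop("ENVI header has no wavelength block")
  if (length(h$wavelength) != h$bands)
    stop("wavelength count does not match the band count")
  if (!h$dtype %in% c(4L, 5L))
    stop("unsupported ENVI data type: ", h$dtype)
  size <- if (h$dtype == 5L) 8L else 4L
  endian <- if (h$byte_order == 0L) "little" else "big"
  n <- h$samples * h$lines * h$bands
  con <- file(path, "rb")
  on.exit(close(con))
  if (h$offset > 0) readBin(con, "raw", h$offset)
  v <- readBin(con, "double", n = n, size = size, endian = endian)
  if (length(v) != n) stop("cube data shorter than the header promises")
  if (any(is.na(v))) stop("cube contains NaN values")
  dims <- switch(h$interleave,
                 bsq = c(h$samples, h$lines, h$bands),
                 bil = c(h$samples, h$bands, h$lines),
                 bip = c(h$bands, h$samples, h$lines),
                 stop("unsupported interleave: ", h$interleave))
  inv <- switch(h$interleave,
                bsq = c(2, 1, 3),
                bil = c(3, 1, 2),
                bip = c(3, 2, 1))
  data <- aperm(array(v, dims), inv)
  dpp <- if (!is.null(h$dpp)) as.numeric(h$dpp)
         else degrees_per_pixel %||% stop("header lacks degrees per pixel")
  spectral_image(data, h$wavelength,
                 kind = h$kind %||% "radiance",
                 degrees_per_pixel = dpp)
}

#' Convert a radiance cube to effective reflectance
#'
#' Pixelwise division of radiance by the direct-illumination spectrum
#' (e.g., as recorded from a neutral reference surface in the scene).
#' Specular pixels may exceed 1; they are warned about, not clipped.
#'
#' @param cube A radiance `spectral_image`.
#' @param reference Illumination `spectrum`, strictly positive on all bands.
#' @return A reflectance `spectral_image`.
#' @export
radiance_to_reflectance <- function(cube, reference) {
  stopifnot(inherits(cube, "spectral_image"), inherits(reference, "spectrum"))
  if (cube$kind != "radiance")
    stop("radiance_to_reflectance expects a radiance cube")
  ref <- resample_spectrum(reference, cube$wavelengths_nm)
  if (any(ref$values <= 0))
    stop("reference spectrum must be strictly positive on all bands")
  d <- dim(cube$data)
  data <- cube$data / rep(ref$values, each = d[1] * d[2])
  if (max(data) > 1 + 0.05)
    warning("reflectance exceeds 1 for some pixels (specular highlights?)")
  out <- spectral_image(data, cube$wavelengths_nm, kind = "radiance",
                        degrees_per_pixel = cube$degrees_per_pixel)
  out$kind <- "reflectance"
  out
}

# Symmetric (edge-including) reflection indices: position 0 maps to 1,
# -1 to 2, n+1 to n, ...; reflections repeat periodically for pads larger
# than the image.
.reflect_index <- function(n, pad_lo, pad_hi) {
  p <- seq.int(1 - pad_lo, n + pad_hi)
  q <- ((p - 1) %% (2 * n)) + 1
  ifelse(q > n, 2 * n + 1 - q, q)
}

.reflect_pad_matrix <- function(m, top, bottom, left, right) {
  m[.reflect_index(nrow(m), top, bottom),
    .reflect_index(ncol(m), left, right), drop = FALSE]
}

#' Block-downsample a cube
#'
#' Non-overlapping factor x factor block means per band ("spatial
#' averaging"). Dimensions not divisible by the factor are reflect-padded
#' to the next multiple first. The angular scale is multiplied by the
#' factor; per-band global means are preserved exactly for divisible
#' dimensions.
#'
#' @param cube A `spectral_image`.
#' @param factor Positive integer.
#' @return The downsampled `spectral_image`.
#' @export
block_downsample <- function(cube, factor) {
  stopifnot(inherits(cube, "spectral_image"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stop("factor must be a positive integer")
  if (factor == 1) return(cube)
  d <- dim(cube$data)
  ph <- (factor - d[1] %% factor) %% factor
  pw <- (factor - d[2] %% factor) %% factor
  h2 <- (d[1] + ph) / factor
  w2 <- (d[2] + pw) / factor
  out <- array(0, c(h2, w2, d[3]))
  for (b in seq_len(d[3])) {
    m <- cube$data[, , b]
    if (ph > 0 || pw > 0) m <- .reflect_pad_matrix(m, 0, ph, 0, pw)
    # mean over factor x factor blocks
    m1 <- colMeans(array(m, c(factor, h2, ncol(m))))          # h2 x w
    out[, , b] <- t(colMeans(array(t(m1), c(factor, w2, h2)))) # h2 x w2
  }
  spectral_image(out, cube$wavelengths_nm, kind = cube$kind,
                 degrees_per_pixel = cube$degrees_per_pixel * factor)
}
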
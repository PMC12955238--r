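#' Freedman-Diaconis bin count
#'
#' Bin width h = 2 IQR n^(-1/3) (quartiles by linear interpolation,
#' type 7), bin count ceil(range / h). Degenerate samples (zero IQR or
#' zero range) get a single bin.
#'
#' @param samples Numeric vector, length >= 2.
#' @return Positive integer bin count.
#' @export
fd_bin_count <- function(samples) {
  n <- length(samples)
  if (n < 2) stop("need at least 2 samples")
  iqr <- diff(stats::quantile(samples, c(0.25, 0.75), names = FALSE,
                              type = 7))
  rng <- max(samples) - min(samples)
  h <- 2 * iqr * n^(-1 / 3)
  if (h <= 0 || rng <= 0) return(1L)
  as.integer(ceiling(rng / h))
}

.edge_hist <- function(samples, edges) {
  # counts over [e_i, e_{i+1}) with the last bin closed
  b <- length(edges) - 1
  idx <- findInterval(samples, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx > b] <- b
  tabulate(idx, nbins = b)
}

.diet_histogram <- function(samples, edges, cone_class = NA_character_) {
  counts <- .edge_hist(samples, edges)
  structure(list(edges = edges, rel_freq = counts / length(samples),
                 n = length(samples), cone_class = cone_class),
            class = "diet_histogram")
}

#' Matched local and global histograms
#'
#' The bin count comes from the Freedman-Diaconis rule applied to the
#' local samples; equal-width edges span the union of the local and global
#' ranges so both histograms share identical bins; frequencies are
#' relative (each sums to 1).
#'
#' @param local Numeric vector of local (foveal-history) samples, n >= 2.
#' @param global Numeric vector of global (whole-image) samples.
#' @param cone_class Optional label ("L", "M", "S").
#' @return List of two `"diet_histogram"` objects: `local`, `global`.
#' @export
matched_histograms <- function(local, global, cone_class = NA_character_) {
  if (length(global) < 1) stop("global sample set is empty")
  b <- fd_bin_count(local)
  lo <- min(local, global)
  hi <- max(local, global)
  if (hi <= lo) hi <- lo + 1e-12
  edges <- seq(lo, hi, length.out = b + 1)
  list(local = .diet_histogram(local, edges, cone_class),
       global = .diet_histogram(global, edges, cone_class))
}

#' Pearson correlation between matched histograms
#'
#' Product-moment correlation between the relative-frequency vectors of
#' two histograms on identical edges. If either vector has zero variance
#' (e.g., a single bin) the correlation is undefined and `NA` is returned.
#'
#' @param local_hist,global_hist `"diet_histogram"` objects with
#'   identical edges.
#' @return Pearson r, or `NA` when undefined.
#' @export
local_global_r <- function(local_hist, global_hist) {
  if (length(local_hist$edges) != length(global_hist$edges) ||
      any(abs(local_hist$edges - global_hist$edges) > 1e-12))
    stop("histograms must share identical edges")
  x <- local_hist$rel_freq
  y <- global_hist$rel_freq
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (is.na(sx) || is.na(sy) || sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}

# log10 with flooring at floor_frac of the global maximum (radiances are
# physically positive; exact zeros only arise in synthetic inputs).
.log_floor <- function(x, global_max, floor_frac = 1e-6) {
  log10(pmax(x, floor_frac * global_max))
}

#' Local-versus-global spectral-diet correlation curve
#'
#' For each end frame n (default 50 to 15,000 in steps of 1) and each cone
#' class, accumulates the log10 cone excitations of the first n foveal
#' samples, builds matched Freedman-Diaconis histograms against the log10
#' excitations of all pixels of the global cone image (edges recomputed at
#' every n, since the bin count depends on the local sample), and records
#' the Pearson correlation between the two relative-frequency vectors.
#'
#' Internally the per-frame histograms are computed by binary search over
#' sorted samples; the result is identical to binning from scratch at
#' every end frame.
#'
#' @param series A `cone_series` from [foveal_series()] (n x 3 matrix).
#' @param global A `cone_image` (the analysis-resolution scene).
#' @param start,stop,step End-frame grid; `stop` is truncated to the
#'   series length with a warning.
#' @param floor_frac Zero-excitation floor as a fraction of the global
#'   per-class maximum, applied before taking logs.
#' @param meta Optional list of labels (scene, observer) carried through.
#' @return Object of class `"correlation_curve"`: list with `end_frames`
#'   and an `r` matrix (length(end_frames) x 3, columns L, M, S; `NA`
#'   where undefined) plus `meta`.
#' @export
correlation_curve <- function(series, global, start = 50, stop = 15000,
                              step = 1, floor_frac = 1e-6, meta = list()) {
  stopifnot(inherits(global, "cone_image"))
  n_series <- nrow(series)
  if (n_series < start) stop("series shorter than the first end frame")
  if (n_series < stop) {
    warning("series shorter than `stop`; truncating")
    stop <- n_series
  }
  ends <- seq.int(start, stop, by = step)
  r <- matrix(NA_real_, length(ends), 3,
              dimnames = list(NULL, c("L", "M", "S")))
  glob <- list(L = global$qL, M = global$qM, S = global$qS)
  for (ci in 1:3) {
    gmax <- max(glob[[ci]])
    gs <- sort(.log_floor(as.numeric(glob[[ci]]), gmax, floor_frac))
    ls_all <- .log_floor(series[, ci], gmax, floor_frac)
    r[, ci] <- .curve_one_class(ls_all, gs, ends)
  }
  ts <- attr(series, "times_s")
  structure(list(end_frames = ends,
                 times_s = if (!is.null(ts)) ts[ends]
                           else rep(NA_real_, length(ends)),
                 r = r, meta = meta),
            class = "correlation_curve")
}

# type-7 quantile of an already sorted vector
.q7 <- function(sorted, p) {
  n <- length(sorted)
  h <- (n - 1) * p + 1
  j <- floor(h)
  g <- h - j
  v <- sorted[j]
  up <- g > 0
  v[up] <- v[up] + g[up] * (sorted[j[up] + 1] - sorted[j[up]])
  v
}

.curve_one_class <- function(local_all, global_sorted, ends) {
  nmax <- ends[length(ends)]
  # running sorted prefix of the local samples, maintained by insertion
  sorted <- sort(local_all[seq_len(ends[1] - 1)])
  gmin <- global_sorted[1]
  gmax <- global_sorted[length(global_sorted)]
  out <- numeric(length(ends))
  ei <- 1L
  for (n in seq.int(ends[1], nmax)) {
    v <- local_all[n]
    sorted <- append(sorted, v, after = findInterval(v, sorted))
    if (n == ends[ei]) {
      # Freedman-Diaconis from the sorted prefix (type-7 quartiles)
      q <- .q7(sorted, c(0.25, 0.75))
      h <- 2 * (q[2] - q[1]) * n^(-1 / 3)
      rng <- sorted[n] - sorted[1]
      b <- if (h <= 0 || rng <= 0) 1L else as.integer(ceiling(rng / h))
      lo <- min(sorted[1], gmin); hi <- max(sorted[n], gmax)
      if (hi <= lo) hi <- lo + 1e-12
      edges <- seq(lo, hi, length.out = b + 1)
      lf <- .sorted_hist_counts(sorted, edges) / n
      gf <- .sorted_hist_counts(global_sorted, edges) / length(global_sorted)
      sl <- stats::sd(lf); sg <- stats::sd(gf)
      out[ei] <- if (is.na(sl) || is.na(sg) || sl == 0 || sg == 0) NA_real_
                 else stats::cor(lf, gf)
      ei <- ei + 1L
      if (ei > length(ends)) break
    }
  }
  out
}

# bin counts over [e_i, e_{i+1}), last bin closed, from a sorted vector
# whose values all lie within [edges[1], edges[last]]; identical to
# .edge_hist but O(bins * log n) via binary search.
.sorted_hist_counts <- function(sorted, edges) {
  b <- length(edges) - 1
  below <- findInterval(edges[seq_len(b)], sorted, left.open = TRUE)
  diff(c(below, length(sorted)))
}

#' Average correlation curves
#'
#' Per-frame mean and standard error (sd / sqrt(k)) over a list of curves
#' sharing the same end-frame grid; undefined (NA) values are skipped.
#'
#' @param curves List of `"correlation_curve"` objects.
#' @return List with `end_frames`, `mean` and `se` matrices (frames x 3).
#' @export
average_curves <- function(curves) {
  if (length(curves) == 0) stop("no curves to average")
  ef <- curves[[1]]$end_frames
  for (cv in curves)
    if (!identical(cv$end_frames, ef))
      stop("curves must share the end-frame grid")
  arr <- simplify2array(lapply(curves, function(cv) cv$r)) # frames x 3 x k
  if (length(curves) == 1) arr <- array(arr, c(dim(arr), 1))
  mu <- apply(arr, c(1, 2), function(v) mean(v, na.rm = TRUE))
  se <- apply(arr, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 1) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  })
  mu[is.nan(mu)] <- NA_real_
  list(end_frames = ef, mean = mu, se = se)
}
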
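#' Gaze trace constructor
#'
#' Timestamped angular gaze positions at a fixed sampling interval
#' (default 20 ms, i.e., 50 Hz). Coordinates are scene-angular: origin at
#' the image top-left corner, x rightward, y downward, in degrees.
#'
#' @param times_s Sample times (s), uniformly spaced.
#' @param x_deg,y_deg Gaze position (deg).
#' @param valid Logical per-sample flag (default all TRUE).
#' @return Object of class `"gaze_trace"`.
#' @export
gaze_trace <- function(times_s, x_deg, y_deg, valid = NULL) {
  n <- length(times_s)
  if (length(x_deg) != n || length(y_deg) != n)
    stop("times, x and y must have the same length")
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (n >= 2) {
    dt <- diff(times_s)
    if (max(dt) - min(dt) > 1e-9)
      stop("gaze timestamps must be uniformly spaced")
  }
  structure(list(times_s = as.numeric(times_s), x_deg = as.numeric(x_deg),
                 y_deg = as.numeric(y_deg), valid = as.logical(valid)),
            class = "gaze_trace")
}

#' @export
print.gaze_trace <- function(x, ...) {
  n <- length(x$times_s)
  cat(sprintf("<gaze_trace> %d samples, %.3g s, %d valid\n",
              n, if (n > 1) x$times_s[n] - x$times_s[1] else 0,
              sum(x$valid)))
  invisible(x)
}

#' @export
length.gaze_trace <- function(x) length(x$times_s)

.trace_interval <- function(trace) {
  if (length(trace$times_s) < 2) stop("trace needs at least 2 samples")
  trace$times_s[2] - trace$times_s[1]
}

#' Angular gaze speeds
#'
#' Per-interval speeds: Euclidean angular displacement between consecutive
#' samples divided by the sampling interval. Length is one less than the
#' trace.
#'
#' @param trace A `gaze_trace` with at least two samples.
#' @return Numeric vector of speeds (deg/s).
#' @export
gaze_speeds <- function(trace) {
  stopifnot(inherits(trace, "gaze_trace"))
  dt <- .trace_interval(trace)
  sqrt(diff(trace$x_deg)^2 + diff(trace$y_deg)^2) / dt
}

#' Exclude fast gaze shifts
#'
#' Marks as invalid every sample whose incoming speed (attributed to the
#' later sample of each consecutive pair) exceeds `vmax`. Excluded samples
#' are skipped by downstream accumulation, never interpolated; the first
#' sample is always kept. `vmax = Inf` disables the exclusion (the
#' robustness re-analysis).
#'
#' @param trace A `gaze_trace`.
#' @param vmax Speed threshold (deg/s), default 5.
#' @return The trace with updated `valid` flags.
#' @export
filter_speed <- function(trace, vmax = 5) {
  stopifnot(inherits(trace, "gaze_trace"))
  if (!is.numeric(vmax) || length(vmax) != 1 || is.na(vmax) || vmax <= 0)
    stop("vmax must be a positive speed")
  if (length(trace$times_s) < 2) return(trace)
  fast <- gaze_speeds(trace) > vmax
  trace$valid <- trace$valid & c(TRUE, !fast)
  trace
}

#' Cumulative speed fraction
#'
#' Fraction of per-interval gaze speeds at or below `v` (the value read
#' off a cumulative speed histogram).
#'
#' @param trace A `gaze_trace`.
#' @param v Speed (deg/s).
#' @return Fraction in `[0, 1]`.
#' @export
cumulative_speed_fraction <- function(trace, v) {
  mean(gaze_speeds(trace) <= v)
}

#' Gaze-model configuration
#'
#' @param step_speed_degps Angular speed of a fixed-step walk (deg/s).
#' @param duration_s Trace duration (s).
#' @param interval_s Sampling interval (s); default 0.02 (50 Hz).
#' @param bounds Image angular extent `c(width_deg, height_deg)`.
#' @param seed RNG seed.
#' @param start Optional start position `c(x_deg, y_deg)`; by default a
#'   uniform random position drawn first from the seed, so all models
#'   configured with the same seed share the same first frame.
#' @return A list of class `"walk_config"`.
#' @export
walk_config <- function(step_speed_degps = 2.3, duration_s = 300,
                        interval_s = 0.02, bounds, seed = 1L,
                        start = NULL) {
  if (step_speed_degps <= 0) stop("step_speed_degps must be > 0")
  if (length(bounds) != 2 || any(bounds <= 0))
    stop("bounds must be positive c(width_deg, height_deg)")
  n <- duration_s / interval_s
  if (abs(n - round(n)) > 1e-9)
    stop("duration must be an integral number of intervals")
  structure(list(step_speed_degps = step_speed_degps,
                 duration_s = duration_s, interval_s = interval_s,
                 bounds = as.numeric(bounds), seed = as.integer(seed),
                 start = start),
            class = "walk_config")
}

# Evaluate fn with a locally seeded RNG, restoring global state after.
.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}

.config_frames <- function(config) as.integer(round(config$duration_s /
                                                      config$interval_s))

.draw_start <- function(config) {
  if (!is.null(config$start)) return(as.numeric(config$start))
  stats::runif(2) * config$bounds
}

#' Random-gaze observer
#'
#' Gaze positions drawn independently and uniformly within the image
#' bounds at every frame (the upper-limit control model).
#'
#' @param config A [walk_config()] (the step speed is ignored).
#' @return A `gaze_trace` with `duration_s / interval_s` frames.
#' @export
simulate_random_gaze <- function(config) {
  stopifnot(inherits(config, "walk_config"))
  n <- .config_frames(config)
  .with_seed(config$seed, function() {
    start <- .draw_start(config)
    x <- c(start[1], stats::runif(n - 1) * config$bounds[1])
    y <- c(start[2], stats::runif(n - 1) * config$bounds[2])
    gaze_trace(seq(0, by = config$interval_s, length.out = n), x, y)
  })
}

#' Random-walk observer
#'
#' Each frame moves a fixed angular distance
#' (`step_speed_degps * interval_s`) in a uniformly random direction;
#' directions are redrawn until the step lands inside the image bounds, so
#' the step length is exactly constant.
#'
#' @param config A [walk_config()].
#' @return A `gaze_trace`.
#' @export
simulate_random_walk <- function(config) {
  stopifnot(inherits(config, "walk_config"))
  step <- config$step_speed_degps * config$interval_s
  if (step >= min(config$bounds))
    stop("step larger than the image bounds")
  n <- .config_frames(config)
  .with_seed(config$seed, function() {
    pos <- .draw_start(config)
    x <- numeric(n); y <- numeric(n)
    x[1] <- pos[1]; y[1] <- pos[2]
    for (i in seq_len(n - 1)) {
      repeat {
        th <- stats::runif(1, 0, 2 * pi)
        nx <- x[i] + step * cos(th)
        ny <- y[i] + step * sin(th)
        if (nx >= 0 && nx <= config$bounds[1] &&
            ny >= 0 && ny <= config$bounds[2]) break
      }
      x[i + 1] <- nx; y[i + 1] <- ny
    }
    gaze_trace(seq(0, by = config$interval_s, length.out = n), x, y)
  })
}

#' Chromatic local-feature observer
#'
#' Finds the 5 x 5 pixel window of the scene with the highest mean CIELAB
#' chroma C* (ties broken by first occurrence in row-major order) and runs
#' a fixed-step random walk confined to a 0.5-degree-diameter disc
#' centered on that window. The default step speed is one third of the
#' recorded modal speed (0.77 deg/s).
#'
#' @param scene A `spectral_image` at analysis resolution.
#' @param config A [walk_config()]; `step_speed_degps` defaults to 0.77 in
#'   [walk_config()] users should set explicitly.
#' @param white Reference white XYZ for C*; default: scene mean XYZ scaled
#'   to Y = 100 (gray-world white).
#' @param disc_diameter_deg Confinement disc diameter (deg), default 0.5.
#' @return A `gaze_trace`.
#' @export
simulate_local_feature <- function(scene, config, white = NULL,
                                   disc_diameter_deg = 0.5) {
  stopifnot(inherits(scene, "spectral_image"), inherits(config, "walk_config"))
  d <- dim(scene$data)
  if (d[1] < 5 || d[2] < 5) stop("scene smaller than 5 x 5 pixels")
  xyz <- cube_to_xyz(scene)
  if (is.null(white)) {
    mu <- c(mean(xyz[, , 1]), mean(xyz[, , 2]), mean(xyz[, , 3]))
    white <- mu * 100 / mu[2]
  }
  cmap <- .chroma_map(xyz, white)
  # mean C* over every 5x5 window; row-major first maximum
  w5 <- .box_filter5(cmap)
  best <- which(t(w5) == max(w5))[1]        # row-major scan
  ctr_col <- (best - 1) %% ncol(w5) + 1
  ctr_row <- (best - 1) %/% ncol(w5) + 1
  dpp <- scene$degrees_per_pixel
  # center pixel of the best 5x5 window; pixel centers at half-integers
  center <- c((ctr_col + 2 - 0.5) * dpp, (ctr_row + 2 - 0.5) * dpp)
  radius <- disc_diameter_deg / 2
  step <- config$step_speed_degps * config$interval_s
  n <- .config_frames(config)
  .with_seed(config$seed, function() {
    .draw_start(config)   # consume the shared start draw; walk starts at center
    x <- numeric(n); y <- numeric(n)
    x[1] <- center[1]; y[1] <- center[2]
    for (i in seq_len(n - 1)) {
      repeat {
        th <- stats::runif(1, 0, 2 * pi)
        nx <- x[i] + step * cos(th)
        ny <- y[i] + step * sin(th)
        inside <- (nx - center[1])^2 + (ny - center[2])^2 <= radius^2 &&
          nx >= 0 && nx <= config$bounds[1] &&
          ny >= 0 && ny <= config$bounds[2]
        if (inside) break
      }
      x[i + 1] <- nx; y[i + 1] <- ny
    }
    gaze_trace(seq(0, by = config$interval_s, length.out = n), x, y)
  })
}

.chroma_map <- function(xyz, white) {
  fx <- .lab_f(xyz[, , 1] / white[1])
  fy <- .lab_f(xyz[, , 2] / white[2])
  fz <- .lab_f(xyz[, , 3] / white[3])
  sqrt((500 * (fx - fy))^2 + (200 * (fy - fz))^2)
}

# Mean over 5x5 windows (valid region), returned as (h-4) x (w-4).
.box_filter5 <- function(m) {
  cs <- function(v) cumsum(c(0, v))
  # 2-d summed-area table
  sat <- apply(m, 2, function(col) cs(col))
  sat <- t(apply(sat, 1, function(row) cs(row)))
  h <- nrow(m); w <- ncol(m)
  i <- seq_len(h - 4); j <- seq_len(w - 4)
  (sat[i + 5, j + 5, drop = FALSE] - sat[i, j + 5, drop = FALSE] -
     sat[i + 5, j, drop = FALSE] + sat[i, j, drop = FALSE]) / 25
}

#' Read / write a gaze trace CSV
#'
#' Plain CSV dialect with columns `time_s,x_deg,y_deg,valid`.
#'
#' @param trace A `gaze_trace`.
#' @param path CSV path.
#' @return `read_gaze` returns a `gaze_trace`; `write_gaze` returns `path`
#'   invisibly.
#' @export
write_gaze <- function(trace, path) {
  stopifnot(inherits(trace, "gaze_trace"))
  utils::write.csv(data.frame(time_s = trace$times_s, x_deg = trace$x_deg,
                              y_deg = trace$y_deg, valid = trace$valid),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gaze
#' @export
read_gaze <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "x_deg", "y_deg")
  if (!all(need %in% names(df)))
    stop("gaze CSV must have columns time_s,x_deg,y_deg[,valid]")
  gaze_trace(df$time_s, df$x_deg, df$y_deg,
             if ("valid" %in% names(df)) df$valid else NULL)
}
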
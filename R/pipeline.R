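#' Spectral-diet analysis of a scene under a gaze trace
#'
#' The package's main entry point for the convergence question: does the
#' history of cone excitations at the foveal center come to resemble the
#' whole scene? Filters fast gaze shifts, renders the scene to cone
#' excitations, extracts the foveal time series and computes the
#' local-versus-global correlation curve for all three cone classes.
#'
#' @param scene A `spectral_image`; reflectance scenes require an
#'   `illuminant`, radiance scenes are used as-is.
#' @param trace A `gaze_trace`.
#' @param illuminant Optional `spectrum` to relight a reflectance scene.
#' @param vmax_degps Gaze-speed exclusion threshold (deg/s); `Inf`
#'   disables the exclusion.
#' @param fundamentals Cone fundamentals.
#' @param start,stop,step End-frame grid for the correlation curve;
#'   `stop` defaults to the number of valid samples.
#' @param profile,sigma0_px Retinal sampling parameters.
#' @param meta Optional labels (scene/observer) carried into the curve.
#' @return Object of class `"spectral_diet"` wrapping the
#'   `correlation_curve`, with the asymptotic correlation (median r over
#'   the last 100 end frames) per cone class.
#' @export
spectral_diet <- function(scene, trace, illuminant = NULL, vmax_degps = 5,
                          fundamentals = cone_fundamentals(),
                          start = 50, stop = NULL, step = 1,
                          profile = default_density_profile(),
                          sigma0_px = 1.0, meta = list()) {
  stopifnot(inherits(scene, "spectral_image"), inherits(trace, "gaze_trace"))
  radiance <- if (scene$kind == "reflectance") {
    if (is.null(illuminant))
      stop("a reflectance scene needs an illuminant")
    apply_illuminant(scene, illuminant)
  } else scene
  trace <- filter_speed(trace, vmax_degps)
  cones <- cone_excitations(radiance, fundamentals)
  series <- foveal_series(cones, trace, profile, sigma0_px)
  if (is.null(stop)) stop <- nrow(series)
  curve <- correlation_curve(series, cones, start = start, stop = stop,
                             step = step, meta = meta)
  tail_n <- min(100, length(curve$end_frames))
  tail_idx <- seq(length(curve$end_frames) - tail_n + 1,
                  length(curve$end_frames))
  asym <- apply(curve$r[tail_idx, , drop = FALSE], 2,
                stats::median, na.rm = TRUE)
  structure(list(curve = curve, asymptote = asym,
                 n_valid = nrow(series), vmax_degps = vmax_degps,
                 meta = meta),
            class = "spectral_diet")
}

#' @export
print.spectral_diet <- function(x, ...) {
  cat(sprintf("<spectral_diet> %d valid frames, %d end frames\n",
              x$n_valid, length(x$curve$end_frames)))
  cat("asymptotic local-global correlation (median of last 100 frames):\n")
  print(signif(x$asymptote, 3))
  invisible(x)
}

#' @export
summary.spectral_diet <- function(object, ...) {
  r <- object$curve$r
  out <- data.frame(cone = colnames(r),
                    r_first = r[1, ],
                    r_last = r[nrow(r), ],
                    r_asymptote = object$asymptote,
                    undefined = colSums(is.na(r)))
  rownames(out) <- NULL
  out
}

#' @export
plot.spectral_diet <- function(x, ...) {
  cv <- x$curve
  t <- if (all(is.na(cv$times_s))) cv$end_frames else cv$times_s
  cols <- c(L = "firebrick", M = "forestgreen", S = "royalblue")
  graphics::matplot(t, cv$r, type = "l", lty = 1, col = cols, log = "x",
                    xlab = "time from gaze onset (frames or s, log axis)",
                    ylab = "local-global histogram correlation r",
                    ylim = c(min(0, min(cv$r, na.rm = TRUE)), 1), ...)
  graphics::legend("bottomright", legend = colnames(cv$r), col = cols,
                   lty = 1, bty = "n")
  invisible(x)
}

#' Adaptation-course analysis (wrapper)
#'
#' Convenience wrapper running [adaptation_timecourse()] for several time
#' constants on one scene/trace pair.
#'
#' @param scene_reflectance,trace,illuminant_cct,vc,... As in
#'   [adaptation_timecourse()].
#' @param tau_s Vector of time constants (s).
#' @return A list of `"adaptation_course"` objects, one per tau.
#' @export
adaptation_course <- function(scene_reflectance, trace,
                              illuminant_cct = 4000, tau_s = c(1, 10),
                              vc = viewing_conditions(), ...) {
  out <- lapply(tau_s, function(tt)
    adaptation_timecourse(scene_reflectance, trace,
                          illuminant_cct = illuminant_cct, tau_s = tt,
                          vc = vc, ...))
  names(out) <- paste0("tau_", tau_s)
  out
}

.resolve_scene <- function(entry) {
  if (is.character(entry)) return(read_cube(entry))
  if (inherits(entry, "spectral_image")) return(entry)
  make_scene(do.call(scene_spec, entry))
}

.resolve_trace <- function(entry, bounds, scene = NULL) {
  if (is.character(entry)) return(read_gaze(entry))
  if (inherits(entry, "gaze_trace")) return(entry)
  model <- entry$model %||% "random"
  if (model == "synthetic") {
    args <- entry[setdiff(names(entry), "model")]
    return(make_gaze(do.call(gaze_spec, args), bounds))
  }
  cfg <- walk_config(step_speed_degps = entry$step %||% 2.3,
                     duration_s = entry$duration_s %||% 300,
                     interval_s = entry$interval_s %||% 0.02,
                     bounds = bounds, seed = entry$seed %||% 1L)
  switch(model,
         random = simulate_random_gaze(cfg),
         walk = simulate_random_walk(cfg),
         feature = simulate_local_feature(scene, cfg),
         stop("unknown gaze model: ", model))
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(config), f)
  unname(tools::md5sum(f))
}

.load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config
}

#' Run a spectral-diet experiment from a configuration
#'
#' For every scene x gaze-source combination: filters gaze speeds, builds
#' the foveal series, computes the correlation curve per cone class and
#' the across-scene average with standard errors. Writes
#' `diet_curves.csv` (columns end_frame, time_s, log10_time_s, cone_class,
#' r, scene, observer) and `diet_summary.json` (config hash, seed,
#' asymptotes) into `config$output_dir`, if set.
#'
#' @param config A list (or YAML path) with fields `scenes`, `gaze`,
#'   optional `illuminant_cct`, `vmax_degps`, `diet` (start/stop/step),
#'   `seed`, `output_dir`.
#' @return Invisibly, a list with the long-format results data frame, the
#'   per-run `spectral_diet` objects and the across-scene average.
#' @export
run_diet_experiment <- function(config) {
  config <- .load_config(config)
  seed <- config$seed %||% 1L
  diet <- config$diet %||% list()
  ill <- daylight_spd(config$illuminant_cct %||% 5571)
  scenes <- lapply(config$scenes, .resolve_scene)
  if (is.null(names(scenes)) || any(!nzchar(names(scenes))))
    names(scenes) <- paste0("scene", seq_along(scenes))
  rows <- list(); runs <- list()
  for (si in seq_along(scenes)) {
    scene <- scenes[[si]]
    bounds <- c(ncol(scene$data[, , 1]), nrow(scene$data[, , 1])) *
      scene$degrees_per_pixel
    for (gi in seq_along(config$gaze)) {
      trace <- .resolve_trace(config$gaze[[gi]], bounds, scene)
      obs <- names(config$gaze)[gi] %||% paste0("gaze", gi)
      if (!nzchar(obs)) obs <- paste0("gaze", gi)
      sd_ <- spectral_diet(scene, trace,
                           illuminant = if (scene$kind == "reflectance")
                             ill else NULL,
                           vmax_degps = config$vmax_degps %||% 5,
                           start = diet$start %||% 50,
                           stop = diet$stop %||% NULL,
                           step = diet$step %||% 1,
                           meta = list(scene = names(scenes)[si],
                                       observer = obs))
      cv <- sd_$curve
      for (cc in colnames(cv$r)) {
        rows[[length(rows) + 1]] <- data.frame(
          end_frame = cv$end_frames, time_s = cv$times_s,
          log10_time_s = log10(cv$times_s), cone_class = cc,
          r = cv$r[, cc], scene = names(scenes)[si], observer = obs)
      }
      runs[[paste(names(scenes)[si], obs, sep = ":")]] <- sd_
    }
  }
  df <- do.call(rbind, rows)
  avg <- average_curves(lapply(runs, function(x) x$curve))
  out <- list(results = df, runs = runs, average = avg,
              config_hash = .config_hash(config), seed = seed)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(df, file.path(config$output_dir, "diet_curves.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = out$config_hash, seed = seed,
           asymptotes = lapply(runs, function(x) as.list(x$asymptote))),
      file.path(config$output_dir, "diet_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

#' Run an adaptation experiment from a configuration
#'
#' For every scene x gaze-source x time-constant combination: relights the
#' scene with the configured daylight illuminant, runs
#' [adaptation_timecourse()] and the uncorrected baseline, and writes
#' `adaptation_timecourse.csv` (columns time_s, tau_s, median_dE, scene,
#' observer) plus `adaptation_summary.json` (jnd, uncorrected baselines,
#' config hash) into `config$output_dir`, if set.
#'
#' @param config A list (or YAML path) with fields `scenes`, `gaze`,
#'   optional `adaptation` (cct, taus, n_times, first_index),
#'   `original_cct`, `seed`, `output_dir`.
#' @return Invisibly, a list with the long-format results data frame, the
#'   course objects, and the uncorrected baselines.
#' @export
run_adaptation_experiment <- function(config) {
  config <- .load_config(config)
  seed <- config$seed %||% 1L
  ad <- config$adaptation %||% list()
  cct <- ad$cct %||% 4000
  taus <- unlist(ad$taus %||% c(1, 10))
  scenes <- lapply(config$scenes, .resolve_scene)
  if (is.null(names(scenes)) || any(!nzchar(names(scenes))))
    names(scenes) <- paste0("scene", seq_along(scenes))
  orig <- daylight_spd(config$original_cct %||% 5571)
  rows <- list(); courses <- list(); uncorr <- list()
  for (si in seq_along(scenes)) {
    scene <- scenes[[si]]
    if (scene$kind != "reflectance")
      stop("adaptation experiments need reflectance scenes")
    bounds <- c(dim(scene$data)[2], dim(scene$data)[1]) *
      scene$degrees_per_pixel
    uncorr[[names(scenes)[si]]] <-
      uncorrected_delta_e(scene, orig, test_cct = cct)
    for (gi in seq_along(config$gaze)) {
      trace <- .resolve_trace(config$gaze[[gi]], bounds, scene)
      obs <- names(config$gaze)[gi] %||% paste0("gaze", gi)
      if (!nzchar(obs)) obs <- paste0("gaze", gi)
      for (tt in taus) {
        crs <- adaptation_timecourse(scene, trace, illuminant_cct = cct,
                                     tau_s = tt,
                                     count = ad$n_times %||% 6,
                                     first_index = ad$first_index %||% 3,
                                     meta = list(scene = names(scenes)[si],
                                                 observer = obs))
        rows[[length(rows) + 1]] <- data.frame(
          time_s = crs$times_s, tau_s = tt, median_dE = crs$median_dE,
          scene = names(scenes)[si], observer = obs)
        courses[[paste(names(scenes)[si], obs, tt, sep = ":")]] <- crs
      }
    }
  }
  df <- do.call(rbind, rows)
  out <- list(results = df, courses = courses,
              uncorrected = uncorr, jnd = 2.46,
              config_hash = .config_hash(config), seed = seed)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(df, file.path(config$output_dir,
                                   "adaptation_timecourse.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(config_hash = out$config_hash, seed = seed, jnd = out$jnd,
           uncorrected_dE = uncorr),
      file.path(config$output_dir, "adaptation_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
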
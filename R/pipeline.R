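#' Standard frame-rate / analysis-window settings
#'
#' The analysis settings used for tracking videos recorded at 50, 20 and
#' 2 fps: the analysis window equals the minimum trajectory length, and the
#' minimum segment length is 60% of the window. Two window sizes are
#' analysed per frame rate so frame-rate and window effects can be
#' separated.
#'
#' @return Data frame with columns `fps`, `video_length_s`, `min_traj_s`,
#'   `window_s`, `min_segment_s`.
#' @export
analysis_settings <- function() {
  data.frame(
    fps = c(50, 50, 20, 20, 2, 2),
    video_length_s = c(20, 20, 30, 30, 250, 250),
    min_traj_s = c(1, 5, 5, 15, 15, 25),
    window_s = c(1, 5, 5, 15, 15, 25),
    min_segment_s = 0.6 * c(1, 5, 5, 15, 15, 25)
  )
}

#' Simulate a labelled ensemble from a compact specification
#'
#' Convenience front end to the trajectory simulator used by
#' [run_analysis()] and configuration files. Two presets are available:
#' \describe{
#'   \item{brownian}{`n_traj` pure-Brownian trajectories with diffusion
#'     coefficient `D` (optionally per-trajectory `lengths`).}
#'   \item{switching}{`n_traj` mode-switching trajectories; each cycles
#'     through the entries of `modes` (a list of per-mode parameter lists
#'     with a `duration_s` each) until `duration_s` seconds are filled.}
#' }
#' `n` is accepted as a synonym for `n_traj` in specs built in R; YAML
#' files must use `n_traj`, since YAML parses a bare `n` key as a boolean.
#'
#' @param spec A list with `preset` (`"brownian"` or `"switching"`) and the
#'   preset's parameters; see Details.
#' @param fps Frame rate.
#' @param seed Integer seed.
#' @return A [traj_ensemble()] of ground-truth trajectories.
#' @export
simulate_ensemble <- function(spec, fps, seed = 1L) {
  dt <- 1 / fps
  preset <- spec$preset
  if (is.null(preset)) stop("simulation spec needs a $preset")
  sigma_loc <- if (is.null(spec$sigma_loc)) 0 else spec$sigma_loc
  n_traj <- if (!is.null(spec$n_traj)) spec$n_traj else spec$n
  if (preset == "brownian") {
    lengths <- if (!is.null(spec$lengths)) as.integer(spec$lengths)
      else rep(as.integer(round(spec$duration_s / dt)) + 1L, n_traj)
    return(matched_brownian_ensemble(spec$D, lengths, dt, seed = seed,
                                     sigma_loc = sigma_loc))
  }
  if (preset == "switching") {
    n <- n_traj
    trajs <- vector("list", n)
    for (i in seq_len(n)) {
      sched <- list()
      total <- 0
      k <- 0L
      while (total < spec$duration_s - 1e-9) {
        entry <- spec$modes[[(k %% length(spec$modes)) + 1L]]
        k <- k + 1L
        dur <- min(entry$duration_s, spec$duration_s - total)
        cfg <- sim_config(entry$mode,
                          D = entry$D,
                          n_steps = 2L,  # overwritten by the scheduler
                          dt = dt,
                          v = entry$v, alpha = entry$alpha, r_c = entry$r_c,
                          sigma_loc = sigma_loc)
        sched[[length(sched) + 1L]] <- list(config = cfg, duration_s = dur)
        total <- total + dur
      }
      trajs[[i]] <- simulate_switching(sched, seed = seed + i * 131L,
                                       id = paste0("sim-", i))
    }
    return(traj_ensemble(trajs, fps = fps, source = "switching simulation"))
  }
  stop("unknown simulation preset '", preset, "'")
}

#' End-to-end trajectory analysis run
#'
#' Orchestrates the full workflow on one recording: duration filtering,
#' drift subtraction, the nonsegmented analysis (per-trajectory anomalous
#' exponents, fast/slow mobility split, displacement PDF, ensemble MSD and
#' Stokes-Einstein viscosity of the fast group), and the segmented analysis
#' (rolling-window classification and segment statistics) for each
#' requested analysis setting. All result tables, a JSON summary, and a run
#' log are written to `output_dir`; a rerun with the same configuration and
#' seed is bit-identical for deterministic stages.
#'
#' @param config A list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{input}{Path to a trajectory table, a [traj_ensemble()], or a
#'       simulation spec list for [simulate_ensemble()].}
#'     \item{fps}{Frame rate (required unless input is an ensemble).}
#'     \item{format, units, pixel_size}{Reader options for file input.}
#'     \item{analysis}{List of analysis settings, each a list/row with
#'       `window_s`, `min_traj_s`, `min_segment_s` (defaults: `min_traj_s =
#'       window_s`, `min_segment_s = 0.6 * window_s`).}
#'     \item{mobility_threshold}{Fast/slow cutoff, µm/sqrt(s); `NULL` skips
#'       the split (single-population input).}
#'     \item{pdf_tau}{Lag for the displacement PDF, s (default: one frame).}
#'     \item{particle_diameter_nm, temperature_K}{Stokes-Einstein inputs
#'       (defaults 100 nm, 293.15 K).}
#'     \item{seed}{Integer seed for simulated input.}
#'     \item{output_dir}{Directory for result files; `NULL` writes nothing.}
#'   }
#' @return A list of class `"trajmodes_run"` with `nonsegmented`,
#'   `segmented` (one entry per analysis setting), `drift`, `viscosity`,
#'   `config`.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  fps <- config$fps
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  # ingest -------------------------------------------------------------
  input <- config$input
  ensemble <- if (inherits(input, "traj_ensemble")) {
    input
  } else if (is.character(input)) {
    read_trajectories(input,
      format = if (is.null(config$format)) "tracker_csv" else config$format,
      fps = fps,
      pixel_size = if (is.null(config$pixel_size)) NA_real_
        else config$pixel_size,
      units = if (is.null(config$units)) "um" else config$units
    )
  } else if (is.list(input)) {
    simulate_ensemble(input, fps = fps, seed = seed)
  } else {
    stop("config$input must be a path, ensemble, or simulation spec")
  }
  if (is.null(fps)) fps <- ensemble$metadata$fps

  analysis <- config$analysis
  if (is.null(analysis)) {
    analysis <- list(list(window_s = 5, min_traj_s = 5, min_segment_s = 3))
  }
  analysis <- lapply(analysis, function(a) {
    if (is.null(a$min_traj_s)) a$min_traj_s <- a$window_s
    if (is.null(a$min_segment_s)) a$min_segment_s <- 0.6 * a$window_s
    if (!(a$min_segment_s <= a$window_s && a$window_s <= a$min_traj_s)) {
      stop("analysis setting must satisfy min_segment_s <= window_s ",
           "<= min_traj_s")
    }
    a
  })

  # global filter at the least demanding setting, then drift correction
  min_traj <- min(vapply(analysis, `[[`, numeric(1), "min_traj_s"))
  ensemble <- filter_min_duration(ensemble, min_traj)
  if (length(ensemble$trajectories) == 0L) {
    stop("no trajectories left after filter_min_duration(min_s = ",
         min_traj, ")")
  }
  ensemble <- subtract_drift(ensemble)
  drift <- attr(ensemble, "drift")

  # nonsegmented analysis ----------------------------------------------
  anomaly <- per_trajectory_anomaly(ensemble)
  mob <- if (!is.null(config$mobility_threshold)) {
    classify_mobility(ensemble, threshold = config$mobility_threshold)
  } else NULL
  fast_ens <- if (!is.null(mob) && length(mob$fast$trajectories) > 0L) {
    mob$fast
  } else ensemble
  ens_msd <- ensemble_msd(fast_ens, max_lag_fraction = 0.25)
  ens_fit <- fit_msd(ens_msd, "normal")
  d_nm <- if (is.null(config$particle_diameter_nm)) 100
    else config$particle_diameter_nm
  temp <- if (is.null(config$temperature_K)) 293.15 else config$temperature_K
  visc <- if (ens_fit$D > 0) {
    stokes_einstein_viscosity(ens_fit$D, d = d_nm, T = temp)
  } else NULL
  pdf_tau <- if (is.null(config$pdf_tau)) 1 / fps else config$pdf_tau
  pdf <- tryCatch(displacement_pdf(ensemble, tau = pdf_tau),
                  error = function(e) NULL)
  nonseg <- list(anomaly = anomaly, mobility = mob, ensemble_msd = ens_msd,
                 ensemble_D = ens_fit$D, viscosity = visc, pdf = pdf)

  # segmented analysis per setting --------------------------------------
  segmented <- lapply(analysis, function(a) {
    ens_a <- filter_min_duration(ensemble, a$min_traj_s)
    cfg <- segmentation_config(a$window_s, a$min_segment_s)
    seg <- segment_ensemble(ens_a, cfg)
    stats <- if (nrow(seg$segments)) mode_proportions(seg) else NULL
    list(window_s = a$window_s, min_traj_s = a$min_traj_s,
         min_segment_s = a$min_segment_s, segmentation = seg, stats = stats)
  })

  res <- structure(
    list(nonsegmented = nonseg, segmented = segmented, drift = drift,
         viscosity = visc, ensemble = ensemble, config = config),
    class = "trajmodes_run"
  )
  if (!is.null(out_dir)) write_run_reports(res, out_dir, seed)
  res
}

write_run_reports <- function(res, out_dir, seed) {
  utils::write.csv(res$nonsegmented$anomaly,
                   file.path(out_dir, "anomaly.csv"), row.names = FALSE)
  if (!is.null(res$nonsegmented$mobility)) {
    utils::write.csv(res$nonsegmented$mobility$table,
                     file.path(out_dir, "mobility.csv"), row.names = FALSE)
  }
  em <- res$nonsegmented$ensemble_msd
  utils::write.csv(
    data.frame(tau_s = em$taus, msd_um2 = em$values, n = em$counts),
    file.path(out_dir, "ensemble_msd.csv"), row.names = FALSE
  )
  for (i in seq_along(res$segmented)) {
    s <- res$segmented[[i]]
    utils::write.csv(
      s$segmentation$segments,
      file.path(out_dir, sprintf("segments_window%gs.csv", s$window_s)),
      row.names = FALSE
    )
  }
  summary <- list(
    seed = seed,
    drift_um_per_s = as.numeric(res$drift),
    ensemble_D_um2_per_s = res$nonsegmented$ensemble_D,
    viscosity_mPa_s = if (!is.null(res$viscosity)) res$viscosity$eta else NA,
    settings = lapply(res$segmented, function(s) {
      st <- s$stats
      list(
        window_s = s$window_s,
        min_segment_s = s$min_segment_s,
        n_segments = nrow(s$segmentation$segments),
        mode_proportions = if (!is.null(st)) as.list(st$mode_proportions),
        median_active_v = if (!is.null(st) &&
                              length(st$velocity_distribution))
          stats::median(st$velocity_distribution) else NA,
        rapid_active_fraction = if (!is.null(st))
          st$rapid_active_fraction else NA
      )
    })
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  writeLines(
    c(paste("trajmodes run,", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
      paste("seed:", seed),
      paste("package version:",
            as.character(utils::packageVersion("trajmodes")))),
    file.path(out_dir, "run_log.txt")
  )
  invisible(out_dir)
}

#' @export
print.trajmodes_run <- function(x, ...) {
  cat("<trajmodes_run>\n")
  cat(sprintf("  trajectories analysed: %d\n",
              length(x$ensemble$trajectories)))
  cat(sprintf("  drift: (%.4g, %.4g) µm/s\n", x$drift[1L], x$drift[2L]))
  cat(sprintf("  ensemble D: %.4g µm²/s\n", x$nonsegmented$ensemble_D))
  if (!is.null(x$viscosity)) {
    cat(sprintf("  viscosity: %.3g mPa·s\n", x$viscosity$eta))
  }
  for (s in x$segmented) {
    cat(sprintf("  window %g s: %d segments\n", s$window_s,
                nrow(s$segmentation$segments)))
  }
  invisible(x)
}

#' Frame-rate / window sensitivity sweep
#'
#' Simulates (or takes) one ensemble at a high frame rate, subsamples it to
#' each requested frame rate, segments it at each analysis window, and
#' tabulates per-setting mode proportions, median active velocity, per-mode
#' median diffusion coefficients and median segment length. This is the
#' synthetic counterpart of comparing one biological data set across
#' recording rates and windows: apparent active velocities fall with slower
#' frame rates and larger windows while diffusion coefficients stay
#' comparable.
#'
#' @param base A [traj_ensemble()] simulated at the highest frame rate, or a
#'   simulation spec for [simulate_ensemble()].
#' @param settings Data frame with columns `fps` and `window_s` (e.g. a
#'   subset of [analysis_settings()]); each fps must divide the base rate.
#' @param base_fps Frame rate of `base` when `base` is a spec.
#' @param seed Integer seed used when simulating.
#' @return Data frame with one row per setting: `fps`, `window_s`,
#'   `status`, `prop_normal`, `prop_active`, `prop_anomalous`,
#'   `prop_confined`, `median_v`, `median_D_normal`, `median_D_active`,
#'   `median_D_anomalous`, `median_segment_s`, `n_segments`.
#' @export
framerate_window_sweep <- function(base, settings, base_fps = NULL,
                                   seed = 1L) {
  if (!inherits(base, "traj_ensemble")) {
    if (is.null(base_fps)) stop("base_fps required when base is a spec")
    base <- simulate_ensemble(base, fps = base_fps, seed = seed)
  }
  base_fps <- base$metadata$fps
  rows <- vector("list", nrow(settings))
  for (i in seq_len(nrow(settings))) {
    fps <- settings$fps[i]
    window_s <- settings$window_s[i]
    factor <- base_fps / fps
    row <- data.frame(
      fps = fps, window_s = window_s, status = "done",
      prop_normal = NA_real_, prop_active = NA_real_,
      prop_anomalous = NA_real_, prop_confined = NA_real_,
      median_v = NA_real_, median_D_normal = NA_real_,
      median_D_active = NA_real_, median_D_anomalous = NA_real_,
      median_segment_s = NA_real_, n_segments = 0L,
      stringsAsFactors = FALSE
    )
    if (abs(factor - round(factor)) > 1e-9) {
      row$status <- "skipped: fps does not divide the base rate"
      rows[[i]] <- row
      next
    }
    if (window_s * fps < 2) {
      row$status <- "skipped: window shorter than 2 frames"
      rows[[i]] <- row
      next
    }
    ens <- subsample(base, as.integer(round(factor)))
    ens <- filter_min_duration(ens, window_s)
    if (length(ens$trajectories) == 0L) {
      row$status <- "skipped: no trajectory spans the window"
      rows[[i]] <- row
      next
    }
    seg <- segment_ensemble(ens, segmentation_config(window_s))
    if (nrow(seg$segments) == 0L) {
      row$status <- "skipped: no segments"
      rows[[i]] <- row
      next
    }
    st <- mode_proportions(seg)
    p <- st$mode_proportions
    row$prop_normal <- p[["normal"]]
    row$prop_active <- p[["active"]]
    row$prop_anomalous <- p[["anomalous"]]
    row$prop_confined <- p[["confined"]]
    row$median_v <- if (length(st$velocity_distribution))
      stats::median(st$velocity_distribution) else NA_real_
    med_or_na <- function(x) if (length(x)) stats::median(x) else NA_real_
    row$median_D_normal <- med_or_na(st$D_distribution$normal)
    row$median_D_active <- med_or_na(st$D_distribution$active)
    row$median_D_anomalous <- med_or_na(st$D_distribution$anomalous)
    row$median_segment_s <- stats::median(seg$segments$duration_s)
    row$n_segments <- nrow(seg$segments)
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
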
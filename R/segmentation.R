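#' Configuration for rolling-window transport-mode segmentation
#'
#' @param window_s Analysis window length, seconds. Only the part of the
#'   trajectory inside the window is analysed at a time.
#' @param min_segment_s Minimum segment length, seconds; defaults to 60% of
#'   the window, the standard ratio across all analysis settings.
#' @param fit_lag_fraction Fraction of each window's lags used for model
#'   fitting (as in [fit_msd()]).
#' @param alpha_sub,alpha_super Anomalous-exponent cutoffs: a window is a
#'   superdiffusion candidate above `alpha_super` and a subdiffusion
#'   candidate below `alpha_sub`.
#' @param alpha_plateau Exponent at or below which a subdiffusive window is
#'   treated as saturated: a confinement plateau resolved inside the window
#'   drives the fitted power-law exponent toward its lower bound, while
#'   genuine subdiffusion keeps a clearly positive exponent.
#' @param margin Relative fit-error improvement (fraction) the active model
#'   must deliver over pure diffusion to claim a superdiffusive window.
#' @return An object of class `"segmentation_config"`.
#' @export
segmentation_config <- function(window_s, min_segment_s = 0.6 * window_s,
                                fit_lag_fraction = 0.25,
                                alpha_sub = 0.7, alpha_super = 1.3,
                                alpha_plateau = 0.25, margin = 0.1) {
  if (window_s <= 0) stop("window_s must be positive")
  if (min_segment_s <= 0 || min_segment_s > window_s) {
    stop("min_segment_s must be in (0, window_s]")
  }
  if (!(alpha_sub < 1 && 1 < alpha_super)) {
    stop("need alpha_sub < 1 < alpha_super")
  }
  structure(
    list(window_s = window_s, min_segment_s = min_segment_s,
         fit_lag_fraction = fit_lag_fraction,
         alpha_sub = alpha_sub, alpha_super = alpha_super,
         alpha_plateau = alpha_plateau, margin = margin),
    class = "segmentation_config"
  )
}

# MSD curve of one window, truncated to the lags the decision rule needs
window_curve <- function(subtraj, config) {
  span <- subtraj$frames[length(subtraj$frames)] - subtraj$frames[1L]
  mlf <- if (config$fit_lag_fraction * span < 4) 1 else
    config$fit_lag_fraction
  time_averaged_msd(subtraj, max_lag_fraction = mlf)
}

# fit a window MSD curve with all candidate models needed by the decision
# rule; returns list(mode, fits)
window_decision <- function(curve, config) {
  nl <- length(curve$taus)
  if (nl < 3L || all(curve$values <= 0)) {
    # degenerate window (e.g. all positions identical): no measurable
    # displacement means the particle is confined below resolution
    return(list(mode = "confined", fits = list()))
  }
  span <- if (is.na(curve$n_positions)) nl else curve$n_positions - 1L
  kmax <- max(3L, as.integer(floor(config$fit_lag_fraction * span)))
  lr <- c(1L, min(kmax, nl))
  # TA-MSD variance grows steeply with lag, so the classifier down-weights
  # long lags; reported segment parameters are refit unweighted
  wts <- 1 / curve$taus^2
  f_anom <- fit_msd(curve, "anomalous", lag_range = lr, weights = wts)
  a <- f_anom$alpha
  if (a > config$alpha_super) {
    f_norm <- fit_msd(curve, "normal", lag_range = lr, weights = wts)
    f_act <- fit_msd(curve, "active", lag_range = lr, weights = wts)
    mode <- if (f_act$fit_error <= (1 - config$margin) * f_norm$fit_error)
      "active" else "normal"
    return(list(mode = mode,
                fits = list(anomalous = f_anom, normal = f_norm,
                            active = f_act)))
  }
  if (a < config$alpha_sub) {
    mode <- "anomalous"
    fits <- list(anomalous = f_anom)
    if (nl >= 4L) {
      f_conf <- fit_msd(curve, "confined", lag_range = c(1L, min(nl, lr[2L])),
                        weights = wts)
      fits$confined <- f_conf
      if (f_conf$converged && a <= config$alpha_plateau &&
          f_conf$fit_error <= f_anom$fit_error) {
        mode <- "confined"
      }
    }
    return(list(mode = mode, fits = fits))
  }
  list(mode = "normal", fits = list(anomalous = f_anom))
}

#' Classify one analysis window
#'
#' Assigns a transport mode to a sub-trajectory from the shape of its
#' time-averaged MSD. The decision rule: fit the power law
#' `MSD = 4 D tau^alpha` (lag-weighted, see [fit_msd()]); if
#' `alpha > alpha_super` the window is active when the active model improves
#' the relative fit error by at least `margin` over pure diffusion, else
#' normal; if `alpha < alpha_sub` it is confined when the exponent has
#' collapsed to the saturation regime (`alpha <= alpha_plateau`) and the
#' confined model fits at least as well as the power law, else anomalous
#' (subdiffusive); otherwise normal. A window with no measurable
#' displacement is classified confined.
#'
#' @param subtraj A [trajectory()] spanning at least the analysis window.
#' @param config A [segmentation_config()].
#' @return The mode name, with the candidate `"msd_fit"`s as attribute
#'   `"fits"`.
#' @export
classify_window <- function(subtraj, config) {
  curve <- window_curve(subtraj, config)
  dec <- window_decision(curve, config)
  structure(dec$mode, fits = dec$fits)
}

window_trajectory <- function(traj, i1, i2) {
  trajectory(traj$x[i1:i2], traj$y[i1:i2], dt = traj$dt,
             frames = traj$frames[i1:i2], id = traj$id)
}

#' Rolling-window transport-mode segmentation of one trajectory
#'
#' Slides an analysis window along the trajectory one frame at a time and
#' classifies each window with [classify_window()]. Each position is then
#' labelled by the majority vote over all windows covering it (ties broken
#' toward the previous position's label, favouring temporal continuity).
#' Runs of identical labels shorter than the minimum segment length are
#' merged into the flanking run whose fitted MSD model describes the run
#' better (ties toward the earlier segment), and each surviving segment's
#' parameters are re-estimated from its own MSD with its mode's model.
#'
#' @param traj A [trajectory()] with duration >= `config$window_s`.
#' @param config A [segmentation_config()].
#' @return An object of class `"traj_segmentation"`: list with `labels`
#'   (per-position mode), `segments` (data frame: `traj_id`, `start_frame`,
#'   `end_frame`, `mode`, `D`, `v`, `alpha`, `duration_s`, `n_positions`),
#'   `window_s`, `config`, `traj`.
#' @export
rolling_classify <- function(traj, config) {
  stopifnot(inherits(traj, "trajectory"),
            inherits(config, "segmentation_config"))
  dt <- traj$dt
  n <- traj_length(traj)
  L <- as.integer(round(config$window_s / dt)) + 1L  # positions per window
  if (L < 4L) L <- 4L
  if (n < L) {
    warning("trajectory '", traj$id, "' shorter than the analysis window; ",
            "no classification")
    return(structure(
      list(labels = rep(NA_character_, n), segments = empty_segments(),
           window_s = config$window_s, config = config, traj = traj),
      class = "traj_segmentation"
    ))
  }
  modes <- transport_modes()
  votes <- matrix(0L, 4L, n, dimnames = list(modes, NULL))
  for (s in seq_len(n - L + 1L)) {
    w <- window_trajectory(traj, s, s + L - 1L)
    md <- window_decision(window_curve(w, config), config)$mode
    votes[md, s:(s + L - 1L)] <- votes[md, s:(s + L - 1L)] + 1L
  }
  labels <- character(n)
  for (j in seq_len(n)) {
    v <- votes[, j]
    top <- modes[v == max(v)]
    labels[j] <- if (length(top) == 1L) top
      else if (j > 1L && labels[j - 1L] %in% top) labels[j - 1L]
      else top[1L]
  }
  labels <- merge_short_runs(traj, labels, config)
  segments <- runs_to_segments(traj, labels, config)
  structure(
    list(labels = labels, segments = segments, window_s = config$window_s,
         config = config, traj = traj),
    class = "traj_segmentation"
  )
}

empty_segments <- function() {
  data.frame(traj_id = character(), start_frame = integer(),
             end_frame = integer(), mode = character(), D = numeric(),
             v = numeric(), alpha = numeric(), duration_s = numeric(),
             n_positions = integer(), stringsAsFactors = FALSE)
}

# residual of `mode`, fitted on the flanking indices, evaluated on the
# run's own MSD curve; Inf when not computable
flank_residual <- function(traj, flank_idx, run_idx, mode) {
  if (length(flank_idx) < 4L || length(run_idx) < 4L) return(Inf)
  out <- tryCatch({
    ffit <- fit_msd(window_trajectory(traj, flank_idx[1L],
                                      flank_idx[length(flank_idx)]), mode)
    run_curve <- time_averaged_msd(
      window_trajectory(traj, run_idx[1L], run_idx[length(run_idx)])
    )
    kmax <- min(length(run_curve$taus), max(3L, ffit$lag_range[2L]))
    tt <- run_curve$taus[seq_len(kmax)]
    sqrt(mean((run_curve$values[seq_len(kmax)] - predict(ffit, tt))^2))
  }, error = function(e) Inf)
  out
}

merge_short_runs <- function(traj, labels, config) {
  dt <- traj$dt
  p_min <- as.integer(round(config$min_segment_s / dt)) + 1L
  repeat {
    r <- rle(labels)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < p_min)
    if (length(short) == 0L) break
    i <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run_idx <- starts[i]:ends[i]
    if (i == 1L) {
      target <- 2L
    } else if (i == length(r$lengths)) {
      target <- i - 1L
    } else {
      res_prev <- flank_residual(traj, starts[i - 1L]:ends[i - 1L], run_idx,
                                 r$values[i - 1L])
      res_next <- flank_residual(traj, starts[i + 1L]:ends[i + 1L], run_idx,
                                 r$values[i + 1L])
      target <- if (res_next < res_prev) i + 1L else i - 1L  # tie: earlier
    }
    labels[run_idx] <- r$values[target]
  }
  labels
}

runs_to_segments <- function(traj, labels, config) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- vector("list", length(r$lengths))
  for (i in seq_along(r$lengths)) {
    seg <- data.frame(
      traj_id = traj$id,
      start_frame = traj$frames[starts[i]],
      end_frame = traj$frames[ends[i]],
      mode = r$values[i],
      D = NA_real_, v = NA_real_, alpha = NA_real_,
      duration_s = (traj$frames[ends[i]] - traj$frames[starts[i]]) * traj$dt,
      n_positions = ends[i] - starts[i] + 1L,
      stringsAsFactors = FALSE
    )
    rows[[i]] <- segment_parameters(seg, traj)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Re-estimate the transport parameters of one segment
#'
#' Refits the segment's own time-averaged MSD with the model of its assigned
#' mode: `D` for every mode, plus `v` for active and `alpha` for anomalous
#' segments. Fit failures leave the parameters `NA`; the segment is
#' retained.
#'
#' @param segment One-row data frame as produced by [rolling_classify()]
#'   (columns `traj_id`, `start_frame`, `end_frame`, `mode`, ...).
#' @param traj The [trajectory()] the segment belongs to.
#' @return The segment row with `D`, `v`, `alpha` filled in.
#' @export
segment_parameters <- function(segment, traj) {
  i1 <- match(segment$start_frame, traj$frames)
  i2 <- match(segment$end_frame, traj$frames)
  if (is.na(i1) || is.na(i2) || i2 - i1 + 1L < 3L) return(segment)
  fit <- tryCatch({
    sub <- window_trajectory(traj, i1, i2)
    cv <- time_averaged_msd(sub)
    # active refits use the quarter-length range uncapped: the (v*tau)^2
    # signature lives at the longest lags the segment resolves, and a lag
    # span fixed in seconds keeps extracted velocities comparable across
    # frame rates; diffusive parameters are most precise at short lags,
    # so the other modes keep the default range
    lr <- if (segment$mode == "active") {
      c(1L, max(3L, as.integer(floor(0.25 * length(cv$taus)))))
    } else NULL
    fit_msd(cv, segment$mode, lag_range = lr)
  }, error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(segment)
  segment$D <- fit$D
  if (segment$mode == "active") segment$v <- fit$v
  if (segment$mode == "anomalous") segment$alpha <- fit$alpha
  segment
}

#' @export
print.traj_segmentation <- function(x, ...) {
  cat(sprintf("<traj_segmentation '%s'> window = %g s, %d segments\n",
              x$traj$id, x$window_s, nrow(x$segments)))
  if (nrow(x$segments)) {
    tab <- table(factor(x$labels, levels = transport_modes()))
    cat("  positions per mode:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.traj_segmentation <- function(x, ...) {
  plot(x$traj, labels = x$labels, ...)
}

#' Segment every trajectory of an ensemble
#'
#' Applies [rolling_classify()] to each trajectory and pools the segment
#' tables. Trajectories shorter than the analysis window are skipped and
#' counted.
#'
#' @param ensemble A [traj_ensemble()].
#' @param config A [segmentation_config()].
#' @return An object of class `"mode_segmentation"`: list with `segments`
#'   (pooled data frame), `labels` (named list of per-position labels),
#'   `n_skipped`, `config`.
#' @export
segment_ensemble <- function(ensemble, config) {
  stopifnot(inherits(ensemble, "traj_ensemble"))
  segs <- list(); labs <- list(); skipped <- 0L
  for (t in ensemble$trajectories) {
    if (traj_duration(t) < config$window_s - 1e-9) {
      skipped <- skipped + 1L
      next
    }
    sc <- rolling_classify(t, config)
    segs[[t$id]] <- sc$segments
    labs[[t$id]] <- sc$labels
  }
  segments <- if (length(segs)) do.call(rbind, segs) else empty_segments()
  rownames(segments) <- NULL
  structure(
    list(segments = segments, labels = labs, n_skipped = skipped,
         config = config),
    class = "mode_segmentation"
  )
}

#' @export
print.mode_segmentation <- function(x, ...) {
  cat(sprintf("<mode_segmentation> %d trajectories, %d segments (%d skipped)\n",
              length(x$labels), nrow(x$segments), x$n_skipped))
  if (nrow(x$segments)) print(mode_proportions(x)$mode_proportions)
  invisible(x)
}

#' Ensemble statistics of a segmentation
#'
#' Summarises a segmentation into the quantities usually reported for
#' intracellular transport: per-mode proportions of positions (weighted by
#' position counts, not segment counts), active-segment velocity
#' distribution, per-mode diffusion-coefficient and segment-length
#' distributions, and the rapid-transport fraction.
#'
#' @param segmentation A `"mode_segmentation"` (or `"traj_segmentation"`),
#'   or a pooled segment data frame.
#' @param rapid_cutoff_D Diffusion-coefficient cutoff (µm²/s) for the
#'   rapid-transport fraction; default 0.01, the conventional threshold for
#'   rapid microtubule-directed transport.
#' @return An object of class `"segment_statistics"`: list with
#'   `mode_proportions` (named, sums to 1 over classified positions),
#'   `velocity_distribution`, `D_distribution` (list per mode),
#'   `segment_length_distribution` (list per mode, seconds),
#'   `rapid_active_fraction`, `n_positions`, `n_segments`.
#' @export
mode_proportions <- function(segmentation, rapid_cutoff_D = 0.01) {
  segments <- if (is.data.frame(segmentation)) segmentation
    else segmentation$segments
  if (nrow(segments) == 0L) stop("no classified segments")
  modes <- transport_modes()
  npos <- tapply(segments$n_positions,
                 factor(segments$mode, levels = modes), sum, default = 0L)
  props <- as.numeric(npos) / sum(segments$n_positions)
  names(props) <- modes
  act <- segments[segments$mode == "active", , drop = FALSE]
  structure(
    list(
      mode_proportions = props,
      velocity_distribution = act$v[is.finite(act$v)],
      D_distribution = lapply(stats::setNames(modes, modes), function(m) {
        d <- segments$D[segments$mode == m]
        d[is.finite(d)]
      }),
      segment_length_distribution = lapply(
        stats::setNames(modes, modes),
        function(m) segments$duration_s[segments$mode == m]
      ),
      rapid_active_fraction = if (nrow(act))
        rapid_transport_fraction(segments, rapid_cutoff_D) else NA_real_,
      n_positions = sum(segments$n_positions),
      n_segments = nrow(segments)
    ),
    class = "segment_statistics"
  )
}

#' @export
print.segment_statistics <- function(x, ...) {
  cat("<segment_statistics>\n  mode proportions:\n")
  print(round(x$mode_proportions, 3))
  if (length(x$velocity_distribution)) {
    cat(sprintf("  median active velocity: %.3g µm/s\n",
                stats::median(x$velocity_distribution)))
  }
  if (is.finite(x$rapid_active_fraction)) {
    cat(sprintf("  rapid active fraction: %.3g\n", x$rapid_active_fraction))
  }
  invisible(x)
}

#' Fraction of active segments in rapid transport
#'
#' Among active segments, the fraction whose diffusion coefficient is at
#' least `cutoff_D`. With the conventional cutoff `D = 0.01` µm²/s this
#' separates rapid microtubule-directed transport from slower
#' microfilament-associated movement.
#'
#' @param segments A pooled segment data frame or a segmentation object.
#' @param cutoff_D Cutoff in µm²/s.
#' @return Fraction in `[0, 1]`; `NA` with a warning when there are no
#'   active segments.
#' @export
rapid_transport_fraction <- function(segments, cutoff_D = 0.01) {
  if (!is.data.frame(segments)) segments <- segments$segments
  act <- segments[segments$mode == "active" & is.finite(segments$D), ,
                  drop = FALSE]
  if (nrow(act) == 0L) {
    warning("no active segments; rapid-transport fraction undefined")
    return(NA_real_)
  }
  mean(act$D >= cutoff_D)
}
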
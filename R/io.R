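#' Read trajectories from a tracking-table file
#'
#' Ingests the flat tables exported by common particle-tracking software.
#' Two dialects are supported:
#' \describe{
#'   \item{`tracker_csv`}{Header row with columns `TRACK_ID`, `FRAME`,
#'     `POSITION_X`, `POSITION_Y`; extra columns are ignored.}
#'   \item{`xy_table`}{Minimal CSV with columns `id`, `frame`, `x`, `y`.}
#' }
#' Rows are grouped by track id and sorted by frame. Tracking gaps (missing
#' frames) are preserved, never interpolated. When `units = "px"` positions
#' are converted to micrometres with `pixel_size`.
#'
#' @param path File to read.
#' @param format `"tracker_csv"` or `"xy_table"`.
#' @param fps Frame rate in frames per second; sets `dt = 1/fps`.
#' @param pixel_size Micrometres per pixel; used only when `units = "px"`.
#' @param units Unit of the position columns: `"um"` (default) or `"px"`.
#' @return A [traj_ensemble()].
#' @seealso [write_trajectories()]
#' @export
read_trajectories <- function(path, format = c("tracker_csv", "xy_table"),
                              fps, pixel_size = NA_real_,
                              units = c("um", "px")) {
  format <- match.arg(format)
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- switch(format,
    tracker_csv = c(id = "TRACK_ID", frame = "FRAME",
                    x = "POSITION_X", y = "POSITION_Y"),
    xy_table = c(id = "id", frame = "frame", x = "x", y = "y")
  )
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  scale <- if (units == "px") {
    if (!is.finite(pixel_size) || pixel_size <= 0) {
      stop("pixel_size must be given (in µm/px) when units = 'px'")
    }
    pixel_size
  } else {
    1
  }
  dt <- 1 / fps
  trajs <- lapply(split(df, df[[cols["id"]]]), function(g) {
    g <- g[order(g[[cols["frame"]]]), , drop = FALSE]
    fr <- as.integer(g[[cols["frame"]]])
    if (anyDuplicated(fr)) {
      stop("duplicate frames within track '", g[[cols["id"]]][1L], "'")
    }
    trajectory(
      x = g[[cols["x"]]] * scale, y = g[[cols["y"]]] * scale,
      dt = dt, frames = fr, id = g[[cols["id"]]][1L]
    )
  })
  traj_ensemble(unname(trajs), fps = fps, pixel_size = pixel_size,
                source = path)
}

#' Write a trajectory ensemble to a tracking-table file
#'
#' Positions are written in micrometres with a deterministic column order;
#' the read/write round trip is loss-free for id, frame, x and y.
#'
#' @param ensemble A [traj_ensemble()].
#' @param path Output file.
#' @param format `"tracker_csv"` or `"xy_table"` (see [read_trajectories()]).
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ensemble, path,
                               format = c("tracker_csv", "xy_table")) {
  format <- match.arg(format)
  rows <- lapply(ensemble$trajectories, function(t) {
    data.frame(id = t$id, frame = t$frames, x = t$x, y = t$y,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), frame = integer(),
               x = numeric(), y = numeric())
  if (format == "tracker_csv") {
    names(df) <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Subsample a trajectory to a lower frame rate
#'
#' Keeps every `factor`-th frame starting at the first and multiplies the
#' frame interval by `factor`, emulating a recording made at `fps / factor`.
#' Frames are selected by frame index (not list position) so tracking gaps
#' stay aligned with real time.
#'
#' @param traj A [trajectory()] or [traj_ensemble()].
#' @param factor Positive integer subsampling factor.
#' @return The subsampled object, with `dt` scaled by `factor`.
#' @export
subsample <- function(traj, factor) UseMethod("subsample")

#' @export
subsample.trajectory <- function(traj, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  if (factor == 1L) return(traj)
  rel <- traj$frames - traj$frames[1L]
  keep <- rel %% factor == 0L
  if (sum(keep) < 2L) {
    stop("fewer than 2 positions survive subsampling of trajectory '",
         traj$id, "'")
  }
  trajectory(
    x = traj$x[keep], y = traj$y[keep], dt = traj$dt * factor,
    frames = rel[keep] %/% factor, id = traj$id
  )
}

#' @export
subsample.traj_ensemble <- function(traj, factor) {
  trajs <- lapply(traj$trajectories, function(t) {
    tryCatch(subsample(t, factor), error = function(e) NULL)
  })
  trajs <- Filter(Negate(is.null), trajs)
  traj_ensemble(unname(trajs), fps = traj$metadata$fps / factor,
                pixel_size = traj$metadata$pixel_size,
                source = traj$metadata$source)
}

#' Keep only sufficiently long trajectories
#'
#' Short trajectories give unreliable MSDs, so analyses are restricted to
#' trajectories whose duration `(N - 1) * dt` is at least `min_s` seconds
#' (boundary inclusive).
#'
#' @param ensemble A [traj_ensemble()].
#' @param min_s Minimum duration in seconds.
#' @return The filtered ensemble (possibly empty).
#' @export
filter_min_duration <- function(ensemble, min_s) {
  if (min_s < 0) stop("min_s must be >= 0")
  keep <- vapply(ensemble$trajectories, function(t) {
    traj_duration(t) >= min_s - 1e-9
  }, logical(1))
  traj_ensemble(unname(ensemble$trajectories[keep]),
                fps = ensemble$metadata$fps,
                pixel_size = ensemble$metadata$pixel_size,
                source = ensemble$metadata$source)
}

#' Apply a constant-velocity drift to a trajectory
#'
#' Shifts position `j` by `drift * (t_j - t_0)`. Mainly useful to create
#' test data for [subtract_drift()], of which it is the inverse when the
#' drift is known.
#'
#' @param traj A [trajectory()] or [traj_ensemble()].
#' @param drift Numeric length-2 drift velocity `(vx, vy)` in µm/s.
#' @return The drifted object.
#' @export
apply_drift <- function(traj, drift) UseMethod("apply_drift")

#' @export
apply_drift.trajectory <- function(traj, drift) {
  stopifnot(length(drift) == 2L, all(is.finite(drift)))
  tt <- traj_times(traj) - traj$frames[1L] * traj$dt
  out <- traj
  out$x <- traj$x + drift[1L] * tt
  out$y <- traj$y + drift[2L] * tt
  out
}

#' @export
apply_drift.traj_ensemble <- function(traj, drift) {
  traj$trajectories <- lapply(traj$trajectories, apply_drift, drift = drift)
  traj
}

#' Estimate and subtract stage drift from an ensemble
#'
#' Stage drift adds a common constant velocity to every trajectory of a
#' recording. The drift velocity is estimated as the ensemble-mean
#' displacement per unit time over all steps of all trajectories,
#' and subtracted cumulatively from every trajectory, so the ensemble-mean
#' net displacement after correction is approximately zero. A single global
#' constant-velocity drift per ensemble (per video) is assumed; per-frame
#' nonparametric drift would be over-fit at typical track counts.
#'
#' @param ensemble A [traj_ensemble()].
#' @return The corrected ensemble, with the estimated drift velocity
#'   attached as attribute `"drift"` (µm/s, length 2).
#' @seealso [apply_drift()]
#' @export
subtract_drift <- function(ensemble) {
  if (length(ensemble$trajectories) == 0L) stop("empty ensemble")
  est <- estimate_drift(ensemble)
  out <- apply_drift(ensemble, -est)
  attr(out, "drift") <- est
  out
}

#' Estimate the constant-velocity stage drift of an ensemble
#'
#' @inheritParams subtract_drift
#' @return Length-2 numeric drift velocity `(vx, vy)` in µm/s.
#' @export
estimate_drift <- function(ensemble) {
  dx <- 0; dy <- 0; tt <- 0; nsteps <- 0L
  for (t in ensemble$trajectories) {
    dfr <- diff(t$frames)
    dx <- dx + sum(diff(t$x))
    dy <- dy + sum(diff(t$y))
    tt <- tt + sum(dfr) * t$dt
    nsteps <- nsteps + length(dfr)
  }
  if (tt <= 0) stop("no time span to estimate drift from")
  if (nsteps < 100L) {
    warning("drift estimate based on only ", nsteps,
            " steps; likely ill-conditioned")
  }
  c(dx, dy) / tt
}
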
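#' Construct a single-particle trajectory
#'
#' A trajectory is the unit of all analysis in this package: a time-ordered
#' sequence of 2D positions recorded at a fixed frame interval. Positions are
#' always stored in micrometres and times in seconds; unit conversion happens
#' only at the I/O boundary (see [read_trajectories()]).
#'
#' Frame indices are 0-based and the time of frame `j` is `j * dt`, so the
#' trajectory duration is `(N - 1) * dt` for `N` gap-free positions. Missing
#' frames (tracking gaps) are allowed: frame indices need not be contiguous,
#' and downstream MSD computation uses actual frame differences rather than
#' assuming contiguity.
#'
#' @param x,y Numeric vectors of positions, micrometres.
#' @param dt Frame interval in seconds (`1 / fps`); must be positive.
#' @param frames Integer frame indices, strictly increasing. Defaults to
#'   `0:(length(x) - 1)`.
#' @param id Trajectory identifier (coerced to character).
#' @return An object of class `"trajectory"`: a list with elements `id`,
#'   `frames`, `x`, `y`, `dt`.
#' @examples
#' tr <- trajectory(x = c(0, 1, 1, 2), y = c(0, 0, 1, 1), dt = 1)
#' traj_duration(tr)
#' @export
trajectory <- function(x, y, dt, frames = NULL, id = "traj-1") {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 2L) stop("a trajectory needs at least 2 positions")
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("positions must be finite")
  }
  if (is.null(frames)) frames <- 0:(n - 1L)
  frames <- as.integer(frames)
  if (length(frames) != n) stop("frames must match the number of positions")
  if (any(diff(frames) <= 0L)) {
    stop("frame indices must be strictly increasing (trajectory '", id, "')")
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a positive number")
  }
  structure(
    list(id = as.character(id), frames = frames, x = x, y = y, dt = dt),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory '%s'> %d positions, dt = %g s, duration = %g s\n",
    x$id, length(x$x), x$dt, traj_duration(x)
  ))
  invisible(x)
}

#' Number of positions in a trajectory
#' @param traj A [trajectory()].
#' @return Integer position count.
#' @export
traj_length <- function(traj) length(traj$x)

#' Trajectory duration in seconds
#'
#' Duration is the time spanned by the recorded frames,
#' `(last frame - first frame) * dt`.
#'
#' @param traj A [trajectory()].
#' @return Duration in seconds.
#' @export
traj_duration <- function(traj) {
  (traj$frames[length(traj$frames)] - traj$frames[1L]) * traj$dt
}

#' Times of the recorded positions
#' @param traj A [trajectory()].
#' @return Numeric vector of times in seconds, `frames * dt`.
#' @export
traj_times <- function(traj) traj$frames * traj$dt

#' Construct a trajectory ensemble
#'
#' An ensemble bundles the trajectories of one recording (one video) with its
#' acquisition metadata. All member trajectories must share the frame
#' interval, and ids must be unique.
#'
#' @param trajectories List of [trajectory()] objects.
#' @param fps Frame rate, frames per second. Defaults to `1 / dt` of the
#'   first trajectory.
#' @param pixel_size Pixel size in micrometres per pixel (metadata only;
#'   positions are already in micrometres).
#' @param source Free-text provenance string.
#' @return An object of class `"traj_ensemble"`.
#' @export
traj_ensemble <- function(trajectories, fps = NULL, pixel_size = NA_real_,
                          source = "") {
  if (!is.list(trajectories)) stop("trajectories must be a list")
  ok <- vapply(trajectories, inherits, logical(1), what = "trajectory")
  if (length(trajectories) > 0L && !all(ok)) {
    stop("all elements must be trajectory objects")
  }
  if (length(trajectories) > 0L) {
    dts <- vapply(trajectories, function(t) t$dt, numeric(1))
    if (max(dts) - min(dts) > 1e-9 * max(dts)) {
      stop("all trajectories in an ensemble must share dt")
    }
    ids <- vapply(trajectories, function(t) t$id, character(1))
    if (anyDuplicated(ids)) stop("trajectory ids must be unique")
    names(trajectories) <- ids
    if (is.null(fps)) fps <- 1 / dts[1L]
  }
  if (is.null(fps)) stop("fps required for an empty ensemble")
  if (fps <= 0) stop("fps must be positive")
  structure(
    list(
      trajectories = trajectories,
      metadata = list(fps = fps, pixel_size = pixel_size, source = source)
    ),
    class = "traj_ensemble"
  )
}

#' @export
print.traj_ensemble <- function(x, ...) {
  n <- length(x$trajectories)
  cat(sprintf(
    "<traj_ensemble> %d trajectories, %g fps%s\n", n, x$metadata$fps,
    if (nzchar(x$metadata$source)) paste0(" [", x$metadata$source, "]") else ""
  ))
  if (n > 0L) {
    len <- vapply(x$trajectories, traj_length, integer(1))
    cat(sprintf("  positions per trajectory: %d-%d (median %g)\n",
                min(len), max(len), stats::median(len)))
  }
  invisible(x)
}

#' @export
length.traj_ensemble <- function(x) length(x$trajectories)

#' @export
`[.traj_ensemble` <- function(x, i) {
  traj_ensemble(x$trajectories[i],
    fps = x$metadata$fps,
    pixel_size = x$metadata$pixel_size,
    source = x$metadata$source
  )
}

#' Plot a trajectory, optionally coloured by transport-mode label
#'
#' @param x A [trajectory()]. If it carries ground-truth mode labels (from the
#'   simulator) or fitted labels, positions are coloured by mode.
#' @param labels Optional character vector of per-position mode labels
#'   overriding any stored ones.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.trajectory <- function(x, labels = NULL, ...) {
  if (is.null(labels)) labels <- x$labels
  graphics::plot(x$x, x$y, type = "l", col = "grey60", asp = 1,
                 xlab = "x (µm)", ylab = "y (µm)",
                 main = paste("trajectory", x$id), ...)
  if (!is.null(labels)) {
    cols <- mode_colors()[labels]
    graphics::points(x$x, x$y, col = cols, pch = 16, cex = 0.5)
    graphics::legend("topright", legend = names(mode_colors()),
                     col = mode_colors(), pch = 16, cex = 0.8, bty = "n")
  }
  invisible(x)
}

#' Transport-mode names used throughout the package
#'
#' @return Character vector `c("normal", "active", "anomalous", "confined")`.
#' @export
transport_modes <- function() c("normal", "active", "anomalous", "confined")

mode_colors <- function() {
  c(normal = "#1b9e77", active = "#d95f02",
    anomalous = "#7570b3", confined = "#e7298a")
}
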
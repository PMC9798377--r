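#' Time-averaged mean squared displacement of one trajectory
#'
#' For a trajectory with positions `(x_j, y_j)` the time-averaged MSD at lag
#' `tau = k * dt` is the mean over all start frames `j` of
#' `(x_{j+k} - x_j)^2 + (y_{j+k} - y_j)^2`. Pairs are formed by actual frame
#' difference, so tracking gaps are handled correctly: a lag with no
#' available pair is omitted, never interpolated. The number of pairs
#' averaged at each lag is recorded, since the accuracy of the estimate
#' decreases towards large lags.
#'
#' @param traj A [trajectory()].
#' @param max_lag_fraction Largest lag to compute, as a fraction of the
#'   trajectory's frame span (0 < fraction <= 1). Defaults to 1 (all lags);
#'   model fitting applies its own, shorter default range.
#' @return An object of class `"msd_curve"`: list with `taus` (s), `values`
#'   (µm²), `counts`, `dt`, `n_positions`, `id`.
#' @examples
#' tr <- trajectory(x = c(0, 1, 1, 2), y = c(0, 0, 1, 1), dt = 1)
#' time_averaged_msd(tr)$values  # 1, 2, 5
#' @export
time_averaged_msd <- function(traj, max_lag_fraction = 1) {
  stopifnot(inherits(traj, "trajectory"))
  if (max_lag_fraction <= 0 || max_lag_fraction > 1) {
    stop("max_lag_fraction must be in (0, 1]")
  }
  f <- traj$frames
  span <- f[length(f)] - f[1L]
  kmax <- max(1L, as.integer(floor(max_lag_fraction * span)))
  contiguous <- length(f) == span + 1L
  taus <- numeric(0); values <- numeric(0); counts <- integer(0)
  for (k in seq_len(kmax)) {
    if (contiguous) {
      n <- length(f) - k
      i1 <- seq_len(n); i2 <- i1 + k
    } else {
      i2 <- match(f + k, f)
      ok <- !is.na(i2)
      if (!any(ok)) next
      i1 <- which(ok); i2 <- i2[ok]
    }
    sq <- (traj$x[i2] - traj$x[i1])^2 + (traj$y[i2] - traj$y[i1])^2
    taus <- c(taus, k * traj$dt)
    values <- c(values, mean(sq))
    counts <- c(counts, length(sq))
  }
  msd_curve(taus, values, counts, dt = traj$dt,
            n_positions = length(f), id = traj$id)
}

#' Construct an MSD curve object
#'
#' Usually produced by [time_averaged_msd()] or [ensemble_msd()]; the
#' constructor is exported so externally computed curves (or textbook
#' examples) can be fed to [fit_msd()].
#'
#' @param taus Time lags, seconds, strictly increasing.
#' @param values MSD values, µm², non-negative.
#' @param counts Displacement pairs (or trajectories) averaged per lag.
#' @param dt Frame interval, seconds.
#' @param n_positions Positions in the source trajectory, if applicable.
#' @param id Source identifier.
#' @return An object of class `"msd_curve"`.
#' @export
msd_curve <- function(taus, values, counts, dt, n_positions = NA_integer_,
                      id = NA_character_) {
  if (length(taus) && any(diff(taus) <= 0)) {
    stop("taus must be strictly increasing")
  }
  structure(
    list(taus = taus, values = values, counts = counts, dt = dt,
         n_positions = n_positions, id = id),
    class = "msd_curve"
  )
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve%s> %d lags, tau = %g..%g s\n",
              if (is.na(x$id)) "" else paste0(" '", x$id, "'"),
              length(x$taus),
              if (length(x$taus)) min(x$taus) else NA,
              if (length(x$taus)) max(x$taus) else NA))
  invisible(x)
}

#' @export
plot.msd_curve <- function(x, log = "xy", ...) {
  keep <- if (grepl("y", log)) x$values > 0 else rep(TRUE, length(x$values))
  graphics::plot(x$taus[keep], x$values[keep], log = log,
                 xlab = expression(tau ~ "(s)"),
                 ylab = expression(MSD ~ (mu * m^2)), pch = 16, ...)
  invisible(x)
}

#' Ensemble-averaged MSD
#'
#' The unweighted mean over per-trajectory time-averaged MSD curves at each
#' common lag. A lag is present in the result if at least one curve
#' contributes to it; `counts` holds the number of contributing curves per
#' lag. For an ensemble of equally long, gap-free trajectories this equals
#' the directly pooled average of all squared displacements.
#'
#' @param curves A list of `"msd_curve"` objects (e.g. from
#'   [time_averaged_msd()]) or a [traj_ensemble()].
#' @param max_lag_fraction Passed to [time_averaged_msd()] when `curves` is
#'   an ensemble.
#' @return An `"msd_curve"` with `counts` = contributing trajectories.
#' @export
ensemble_msd <- function(curves, max_lag_fraction = 1) {
  if (inherits(curves, "traj_ensemble")) {
    curves <- lapply(curves$trajectories, time_averaged_msd,
                     max_lag_fraction = max_lag_fraction)
  }
  if (length(curves) == 0L) stop("need at least one MSD curve")
  ok <- vapply(curves, inherits, logical(1), "msd_curve")
  if (!all(ok)) stop("all elements must be msd_curve objects")
  dts <- vapply(curves, `[[`, numeric(1), "dt")
  if (max(dts) - min(dts) > 1e-9 * max(dts)) {
    stop("curves must share a common dt")
  }
  ks <- sort(unique(unlist(lapply(curves, function(cv) {
    as.integer(round(cv$taus / cv$dt))
  }))))
  vals <- numeric(length(ks)); cnts <- integer(length(ks))
  for (i in seq_along(ks)) {
    contrib <- vapply(curves, function(cv) {
      j <- match(ks[i], as.integer(round(cv$taus / cv$dt)))
      if (is.na(j)) NA_real_ else cv$values[j]
    }, numeric(1))
    contrib <- contrib[!is.na(contrib)]
    vals[i] <- mean(contrib)
    cnts[i] <- length(contrib)
  }
  msd_curve(ks * dts[1L], vals, cnts, dt = dts[1L],
            id = "ensemble")
}
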
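#' Per-trajectory anomalous-diffusion scan
#'
#' Fits the power-law model `MSD = 4 D tau^alpha` to every trajectory's
#' time-averaged MSD over the default short-lag range and tabulates the
#' per-trajectory diffusion coefficients `D_i` and anomalous exponents
#' `alpha_i`. The shape of these distributions separates transport regimes:
#' for a homogeneous Brownian population the `alpha_i` are narrowly
#' distributed around 1 and their spread is explained by finite trajectory
#' length alone (compare against [matched_brownian_ensemble()]).
#'
#' Individual fit failures are recorded (`converged = FALSE`), not fatal.
#'
#' @param ensemble A [traj_ensemble()] (normally after
#'   [filter_min_duration()]).
#' @param lag_range Lag range passed to [fit_msd()]; `NULL` for its
#'   short-lag default.
#' @return A data frame with columns `id`, `n_positions`, `D`, `alpha`,
#'   `fit_error`, `converged`.
#' @export
per_trajectory_anomaly <- function(ensemble, lag_range = NULL) {
  stopifnot(inherits(ensemble, "traj_ensemble"))
  rows <- lapply(ensemble$trajectories, function(t) {
    res <- tryCatch({
      cv <- time_averaged_msd(t)
      f <- fit_msd(cv, "anomalous", lag_range = lag_range)
      data.frame(id = t$id, n_positions = traj_length(t), D = f$D,
                 alpha = f$alpha, fit_error = f$fit_error,
                 converged = f$converged, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(id = t$id, n_positions = traj_length(t), D = NA_real_,
                 alpha = NA_real_, fit_error = NA_real_, converged = FALSE,
                 stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative displacement of a trajectory
#'
#' The spatial extent `dx = max(x) - min(x)` (and likewise `dy`), scaled by
#' the square root of the trajectory duration. For free diffusion the extent
#' grows as the square root of time, so this scaling makes slow and fast
#' particles directly comparable across trajectory lengths.
#'
#' @param traj A [trajectory()].
#' @return Named numeric `c(scaled_dx, scaled_dy)` in µm/sqrt(s).
#' @export
relative_displacement <- function(traj) {
  dur <- traj_duration(traj)
  if (dur <= 0) stop("trajectory duration must be positive")
  c(scaled_dx = (max(traj$x) - min(traj$x)) / sqrt(dur),
    scaled_dy = (max(traj$y) - min(traj$y)) / sqrt(dur))
}

#' Split an ensemble into fast and slow particles
#'
#' In tracking videos of particles added to cells, trajectories typically
#' form two groups by scaled relative displacement: fast particles diffusing
#' in the medium and slow cell-associated particles. A trajectory is "fast"
#' iff `max(scaled_dx, scaled_dy) > threshold`. With `threshold = NULL` the
#' cutoff is placed automatically at the minimum density between the two
#' modes of the pooled scaled-displacement distribution; if that
#' distribution is unimodal an error asks for an explicit threshold.
#'
#' @param ensemble A [traj_ensemble()].
#' @param threshold Cutoff in µm/sqrt(s), or `NULL` for automatic placement.
#' @return A list with elements `fast` and `slow` ([traj_ensemble()]s),
#'   `threshold`, and `table` (per-trajectory scaled displacements and
#'   group).
#' @export
classify_mobility <- function(ensemble, threshold = NULL) {
  stopifnot(inherits(ensemble, "traj_ensemble"))
  if (length(ensemble$trajectories) == 0L) stop("empty ensemble")
  rd <- t(vapply(ensemble$trajectories, relative_displacement, numeric(2)))
  score <- pmax(rd[, 1L], rd[, 2L])
  if (is.null(threshold)) {
    threshold <- bimodal_valley(score)
  } else if (threshold <= 0) {
    stop("threshold must be positive")
  }
  fast <- score > threshold
  tab <- data.frame(
    id = vapply(ensemble$trajectories, `[[`, character(1), "id"),
    scaled_dx = rd[, 1L], scaled_dy = rd[, 2L],
    group = ifelse(fast, "fast", "slow"), stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  list(
    fast = ensemble[which(fast)],
    slow = ensemble[which(!fast)],
    threshold = threshold,
    table = tab
  )
}

# Valley between the two major modes of a 1D sample, found on a kernel
# density estimate in log space (displacement scores are positive and
# typically spread over decades).
bimodal_valley <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) < 4L) stop("too few trajectories for automatic threshold")
  d <- stats::density(log(x))
  y <- d$y
  n <- length(y)
  is_max <- which(y > c(-Inf, y[-n]) & y >= c(y[-1L], -Inf))
  is_max <- is_max[y[is_max] > 0.05 * max(y)]
  if (length(is_max) < 2L) {
    stop("scaled-displacement distribution looks unimodal; ",
         "supply an explicit threshold")
  }
  peaks <- is_max[order(y[is_max], decreasing = TRUE)][1:2]
  lo <- min(peaks); hi <- max(peaks)
  valley <- lo + which.min(y[lo:hi]) - 1L
  exp(d$x[valley])
}

#' Displacement probability density at a fixed lag
#'
#' Pools the 1D axis displacements (x and y) of all trajectories at lag
#' `tau`, bins them to a probability density, fits a zero-mean Gaussian, and
#' scores non-Gaussianity as the excess kurtosis of the pooled sample
#' (0 for a Gaussian). For normal diffusion the density is Gaussian with
#' variance `2 D tau` per axis; mixtures of mobilities show heavy tails
#' (positive excess kurtosis).
#'
#' @param ensemble A [traj_ensemble()].
#' @param tau Time lag, seconds (rounded to the nearest frame lag).
#' @param bins Number of histogram bins.
#' @return An object of class `"displacement_pdf"`: list with `tau`,
#'   `bin_centers`, `density`, `gaussian_sigma`, `non_gaussianity`,
#'   `n_samples`.
#' @export
displacement_pdf <- function(ensemble, tau, bins = 50) {
  stopifnot(inherits(ensemble, "traj_ensemble"))
  dt <- ensemble$trajectories[[1L]]$dt
  k <- max(1L, as.integer(round(tau / dt)))
  disp <- unlist(lapply(ensemble$trajectories, function(t) {
    i2 <- match(t$frames + k, t$frames)
    ok <- !is.na(i2)
    c(t$x[i2[ok]] - t$x[ok], t$y[i2[ok]] - t$y[ok])
  }))
  if (length(disp) < 100L) {
    stop("only ", length(disp), " displacement samples at lag ", k * dt,
         " s; need at least 100")
  }
  if (stats::sd(disp) == 0) {
    stop("degenerate displacement sample (zero spread) at lag ", k * dt, " s")
  }
  h <- graphics::hist(disp, breaks = bins, plot = FALSE)
  structure(
    list(
      tau = k * dt,
      bin_centers = h$mids,
      density = h$density,
      gaussian_sigma = sqrt(mean(disp^2)),  # zero-mean Gaussian MLE
      non_gaussianity = excess_kurtosis(disp),
      n_samples = length(disp)
    ),
    class = "displacement_pdf"
  )
}

#' @export
print.displacement_pdf <- function(x, ...) {
  cat(sprintf(
    "<displacement_pdf> tau = %g s, n = %d, sigma = %.4g µm, excess kurtosis = %.3g\n",
    x$tau, x$n_samples, x$gaussian_sigma, x$non_gaussianity
  ))
  invisible(x)
}

#' @export
plot.displacement_pdf <- function(x, ...) {
  graphics::plot(x$bin_centers, x$density, type = "h", log = "",
                 xlab = expression(Delta * x ~ (mu * m)),
                 ylab = expression(density ~ (mu * m^{-1})), ...)
  g <- stats::dnorm(x$bin_centers, sd = x$gaussian_sigma)
  graphics::lines(x$bin_centers, g, col = "firebrick", lwd = 2, lty = 2)
  invisible(x)
}

excess_kurtosis <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  mean(x^4) / m2^2 - 3
}

#' Stokes-Einstein viscosity from a diffusion coefficient
#'
#' For a sphere of hydrodynamic diameter `d` diffusing with coefficient `D`
#' at temperature `T`, the Stokes-Einstein relation `D = k_B T / (3 pi eta
#' d)` gives the viscosity of the surrounding medium — the passive
#' microrheology readout of tracking data.
#'
#' @param D Diffusion coefficient, µm²/s.
#' @param d Hydrodynamic diameter, nm.
#' @param T Temperature, K (default 293.15, room temperature).
#' @return An object of class `"viscosity_estimate"`: list with `eta`
#'   (mPa·s), `D`, `d`, `T`.
#' @examples
#' stokes_einstein_viscosity(D = 3, d = 100, T = 293)$eta  # about 1.4
#' @export
stokes_einstein_viscosity <- function(D, d, T = 293.15) {
  if (D <= 0 || d <= 0 || T <= 0) stop("D, d and T must be positive")
  k_B <- 1.380649e-23                 # J/K
  D_si <- D * 1e-12                   # µm²/s -> m²/s
  d_si <- d * 1e-9                    # nm -> m
  eta_pa_s <- k_B * T / (3 * pi * D_si * d_si)
  structure(
    list(eta = eta_pa_s * 1e3, D = D, d = d, T = T),
    class = "viscosity_estimate"
  )
}

#' @export
print.viscosity_estimate <- function(x, ...) {
  cat(sprintf(
    "<viscosity_estimate> eta = %.3g mPa·s (D = %g µm²/s, d = %g nm, T = %g K)\n",
    x$eta, x$D, x$d, x$T
  ))
  invisible(x)
}
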
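#' Simulation configuration for one transport mode
#'
#' Collects the parameters of one of the four transport modes used across
#' intracellular single-particle-tracking studies:
#' \describe{
#'   \item{normal}{Brownian motion; independent Gaussian steps per axis with
#'     variance `2 * D * dt`, so the 2D MSD is `4 D tau`.}
#'   \item{active}{Brownian motion plus directed transport at constant speed
#'     `v` along a persistent heading; MSD `4 D tau + (v tau)^2`.}
#'   \item{anomalous}{Subdiffusion as fractional Brownian motion per axis
#'     with Hurst exponent `alpha / 2`, scaled so the MSD is
#'     `4 D tau^alpha` (units of `D` then µm²/s^alpha).}
#'   \item{confined}{Brownian steps reflected at a circle of radius `r_c`
#'     centred on the segment start; the MSD plateaus near `r_c^2`.}
#' }
#' Localization noise (the camera's per-frame position error) is added after
#' path generation as i.i.d. zero-mean Gaussian noise with standard deviation
#' `sigma_loc` per axis.
#'
#' @param mode One of `"normal"`, `"active"`, `"anomalous"`, `"confined"`.
#' @param D Diffusion coefficient, µm²/s; must be non-negative.
#' @param n_steps Number of positions to generate (>= 2).
#' @param dt Frame interval, seconds.
#' @param v Active transport speed, µm/s (required for `mode = "active"`).
#' @param alpha Anomalous exponent in (0, 2) (required for `"anomalous"`).
#' @param r_c Confinement radius, µm (required for `"confined"`).
#' @param sigma_loc Localization-error standard deviation per axis, µm.
#' @param seed Integer seed for reproducibility, or `NULL` to use the
#'   current RNG state.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(mode = c("normal", "active", "anomalous", "confined"),
                       D, n_steps, dt, v = NULL, alpha = NULL, r_c = NULL,
                       sigma_loc = 0, seed = NULL) {
  if (length(mode) == 1L && !mode %in% transport_modes()) {
    stop("unknown mode '", mode, "'")
  }
  mode <- match.arg(mode)
  if (!is.numeric(D) || D < 0) stop("D must be >= 0")
  if (dt <= 0) stop("dt must be > 0")
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop("n_steps must be >= 2")
  if (sigma_loc < 0) stop("sigma_loc must be >= 0")
  if (mode == "active") {
    if (is.null(v) || v < 0) stop("mode 'active' requires a speed v >= 0")
  }
  if (mode == "anomalous") {
    if (is.null(alpha) || alpha <= 0 || alpha >= 2) {
      stop("mode 'anomalous' requires 0 < alpha < 2")
    }
  }
  if (mode == "confined") {
    if (is.null(r_c) || r_c <= 0) stop("mode 'confined' requires r_c > 0")
  }
  structure(
    list(mode = mode, D = D, v = v, alpha = alpha, r_c = r_c,
         n_steps = n_steps, dt = dt, sigma_loc = sigma_loc, seed = seed),
    class = "sim_config"
  )
}

# Noiseless 2D path for one mode, started at `origin`, using the current RNG
# stream. Returns an n_steps x 2 matrix of positions.
sim_path <- function(config, origin = c(0, 0)) {
  n <- config$n_steps
  dt <- config$dt
  D <- config$D
  pos <- matrix(0, n, 2L)
  switch(config$mode,
    normal = {
      sd <- sqrt(2 * D * dt)
      pos[, 1L] <- cumsum(c(0, stats::rnorm(n - 1L, sd = sd)))
      pos[, 2L] <- cumsum(c(0, stats::rnorm(n - 1L, sd = sd)))
    },
    active = {
      theta <- stats::runif(1L, 0, 2 * pi)  # persistent heading, per segment
      sd <- sqrt(2 * D * dt)
      step <- config$v * dt
      pos[, 1L] <- cumsum(c(0, stats::rnorm(n - 1L, sd = sd) +
                              step * cos(theta)))
      pos[, 2L] <- cumsum(c(0, stats::rnorm(n - 1L, sd = sd) +
                              step * sin(theta)))
    },
    anomalous = {
      H <- config$alpha / 2
      scale <- sqrt(2 * D) * dt^H
      pos[, 1L] <- c(0, scale * cumsum(fbm_increments(n - 1L, H)))
      pos[, 2L] <- c(0, scale * cumsum(fbm_increments(n - 1L, H)))
    },
    confined = {
      sd <- sqrt(2 * D * dt)
      r_c <- config$r_c
      sx <- stats::rnorm(n - 1L, sd = sd)
      sy <- stats::rnorm(n - 1L, sd = sd)
      px <- 0; py <- 0
      for (j in seq_len(n - 1L)) {
        qx <- px + sx[j]; qy <- py + sy[j]
        r <- sqrt(qx^2 + qy^2)
        if (r > r_c) {  # radial reflection at the circular boundary
          rr <- 2 * r_c - r
          if (rr < 0) rr <- r_c * abs(rr / r_c) %% r_c
          qx <- qx * rr / r; qy <- qy * rr / r
        }
        px <- qx; py <- qy
        pos[j + 1L, 1L] <- px; pos[j + 1L, 2L] <- py
      }
    }
  )
  sweep(pos, 2L, origin, `+`)
}

#' Simulate a labelled trajectory under one transport mode
#'
#' Generates a 2D trajectory from a [sim_config()] and attaches per-position
#' ground-truth mode labels, so classification and parameter-recovery code
#' can be validated without microscopy data. Localization noise is added
#' after path generation. The same seed and configuration always give a
#' bit-identical trajectory.
#'
#' @param config A [sim_config()].
#' @param id Trajectory id.
#' @return A `"trajectory"` with extra fields `labels` (per-position mode)
#'   and `generating_params` (one-row data frame of the true parameters);
#'   class `c("gt_trajectory", "trajectory")`.
#' @examples
#' tr <- simulate_trajectory(sim_config("normal", D = 3, n_steps = 100,
#'                                      dt = 0.02, seed = 1))
#' table(tr$labels)
#' @export
simulate_trajectory <- function(config, id = "sim-1") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  pos <- sim_path(config)
  n <- config$n_steps
  if (config$sigma_loc > 0) {
    pos <- pos + matrix(stats::rnorm(2L * n, sd = config$sigma_loc), n, 2L)
  }
  out <- trajectory(pos[, 1L], pos[, 2L], dt = config$dt, id = id)
  out$labels <- rep(config$mode, n)
  out$generating_params <- params_row(config, 1L, n)
  class(out) <- c("gt_trajectory", "trajectory")
  out
}

params_row <- function(config, start, end) {
  data.frame(
    mode = config$mode,
    D = config$D,
    v = if (is.null(config$v)) NA_real_ else config$v,
    alpha = if (is.null(config$alpha)) NA_real_ else config$alpha,
    r_c = if (is.null(config$r_c)) NA_real_ else config$r_c,
    start = start, end = end,
    stringsAsFactors = FALSE
  )
}

#' Simulate a mode-switching trajectory
#'
#' Intracellular cargo alternates between transport modes ("stop and go"
#' movement); this generator concatenates segments of the four modes into
#' one continuous trajectory. Each schedule entry contributes
#' `round(duration_s / dt)` positions; each segment starts where the
#' previous one ended (continuous in position, instantaneous in parameters).
#'
#' @param schedule List of entries `list(config = sim_config, duration_s =
#'   seconds)`. All configs must share `dt`.
#' @param seed Integer seed; defaults to the first entry's seed. Per-segment
#'   streams are derived deterministically from it.
#' @param id Trajectory id.
#' @return A `"gt_trajectory"` whose `labels` follow the schedule and whose
#'   `generating_params` has one row per segment.
#' @export
simulate_switching <- function(schedule, seed = NULL, id = "sim-1") {
  if (length(schedule) == 0L) stop("empty schedule")
  configs <- lapply(schedule, `[[`, "config")
  durs <- vapply(schedule, `[[`, numeric(1), "duration_s")
  ok <- vapply(configs, inherits, logical(1), "sim_config")
  if (!all(ok)) stop("each schedule entry needs a sim_config in $config")
  dts <- vapply(configs, `[[`, numeric(1), "dt")
  if (max(dts) - min(dts) > 1e-12) {
    stop("all schedule entries must share dt")
  }
  dt <- dts[1L]
  counts <- as.integer(round(durs / dt))
  if (sum(counts) * dt < 2 * dt) stop("total duration must be >= 2 * dt")
  if (is.null(seed)) seed <- configs[[1L]]$seed
  keep <- counts > 0L
  configs <- configs[keep]; counts <- counts[keep]
  pos <- NULL
  labels <- character(0)
  params <- NULL
  origin <- c(0, 0)
  for (k in seq_along(configs)) {
    cfg <- configs[[k]]
    if (!is.null(seed)) set.seed(seed + (k - 1L) * 10007L)
    if (k == 1L) {
      cfg$n_steps <- counts[k]
      seg <- sim_path(cfg, origin = origin)
    } else {
      # simulate one extra step and drop the anchor so the segment
      # contributes exactly counts[k] new positions from the previous end
      cfg$n_steps <- counts[k] + 1L
      seg <- sim_path(cfg, origin = origin)[-1L, , drop = FALSE]
    }
    origin <- seg[nrow(seg), ]
    start <- length(labels) + 1L
    pos <- rbind(pos, seg)
    labels <- c(labels, rep(cfg$mode, nrow(seg)))
    params <- rbind(params, params_row(cfg, start, length(labels)))
  }
  n <- nrow(pos)
  sig <- vapply(configs, `[[`, numeric(1), "sigma_loc")
  sigma_per_pos <- rep(sig, counts)
  if (any(sigma_per_pos > 0)) {
    pos <- pos + matrix(stats::rnorm(2L * n), n, 2L) * sigma_per_pos
  }
  out <- trajectory(pos[, 1L], pos[, 2L], dt = dt, id = id)
  out$labels <- labels
  out$generating_params <- params
  class(out) <- c("gt_trajectory", "trajectory")
  out
}

#' Matched Brownian control ensemble
#'
#' Generates pure-Brownian trajectories with a common diffusion coefficient
#' but the same number and individual lengths as an experimental data set.
#' This is the standard control showing how much of the spread of
#' per-trajectory `D_i` and `alpha_i` estimates is explained by finite
#' trajectory length alone.
#'
#' @param D Common diffusion coefficient, µm²/s.
#' @param lengths Integer vector of frame counts, one per trajectory
#'   (all >= 2).
#' @param dt Frame interval, seconds.
#' @param seed Integer seed.
#' @param sigma_loc Localization noise sd per axis, µm.
#' @return A [traj_ensemble()] of `"gt_trajectory"` objects.
#' @export
matched_brownian_ensemble <- function(D, lengths, dt, seed = NULL,
                                      sigma_loc = 0) {
  if (length(lengths) == 0L) stop("lengths must be non-empty")
  if (any(lengths < 2L)) stop("all lengths must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  trajs <- vector("list", length(lengths))
  for (i in seq_along(lengths)) {
    cfg <- sim_config("normal", D = D, n_steps = lengths[i], dt = dt,
                      sigma_loc = sigma_loc, seed = NULL)
    trajs[[i]] <- simulate_trajectory(cfg, id = paste0("sim-", i))
  }
  traj_ensemble(trajs, fps = 1 / dt, source = "matched brownian control")
}

#' Fractional Gaussian noise increments
#'
#' Samples `n` increments of fractional Brownian motion with Hurst exponent
#' `H` at unit spacing and unit variance, by Davies-Harte circulant
#' embedding (exact covariance, O(n log n)); falls back to a Cholesky
#' factorisation of the covariance matrix in the rare case the circulant
#' embedding is not non-negative definite. Draws from the current RNG
#' stream. `H = 0.5` reduces to i.i.d. standard normal increments.
#'
#' @param n Number of increments.
#' @param H Hurst exponent in (0, 1).
#' @return Numeric vector of length `n`.
#' @keywords internal
fbm_increments <- function(n, H) {
  stopifnot(n >= 1L, H > 0, H < 1)
  if (abs(H - 0.5) < 1e-12) return(stats::rnorm(n))
  k <- 0:n
  gamma <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) +
                    abs(k - 1)^(2 * H))
  # circulant first row: gamma_0..gamma_n, gamma_{n-1}..gamma_1
  g <- c(gamma, gamma[n:2])
  lambda <- Re(stats::fft(g))
  if (min(lambda) < -1e-8 * max(lambda)) {
    # exact fallback: Cholesky of the n x n fGn covariance
    S <- outer(1:n, 1:n, function(i, j) {
      d <- abs(i - j)
      0.5 * (abs(d + 1)^(2 * H) - 2 * d^(2 * H) + abs(d - 1)^(2 * H))
    })
    L <- chol(S + diag(1e-12, n))
    return(as.numeric(crossprod(L, stats::rnorm(n))))
  }
  lambda[lambda < 0] <- 0
  m <- 2L * n
  w <- complex(length.out = m)
  z1 <- stats::rnorm(n - 1L); z2 <- stats::rnorm(n - 1L)
  w[1L] <- sqrt(lambda[1L]) * stats::rnorm(1L)
  w[n + 1L] <- sqrt(lambda[n + 1L]) * stats::rnorm(1L)
  idx <- 2:n
  w[idx] <- sqrt(lambda[idx] / 2) * complex(real = z1, imaginary = z2)
  w[m + 2L - idx] <- Conj(w[idx])
  x <- Re(stats::fft(w)) / sqrt(m)
  x[1:n]
}
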
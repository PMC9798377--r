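# Small simulation helpers shared across test files.

brownian_traj <- function(D = 3, n = 500, dt = 0.02, seed = 1, ...) {
  simulate_trajectory(sim_config("normal", D = D, n_steps = n, dt = dt,
                                 seed = seed, ...))
}

brownian_ensemble <- function(D = 3, n_traj = 20, n = 500, dt = 0.02,
                              seed = 1) {
  matched_brownian_ensemble(D, rep(as.integer(n), n_traj), dt, seed = seed)
}

# deterministic zig-zag trajectory with no randomness
stationary_traj <- function(n = 10, dt = 1) {
  trajectory(rep(1.5, n), rep(-2, n), dt = dt)
}

# brute-force reference for the time-averaged MSD: double loop over all
# position pairs, independent of the vectorised implementation
msd_bruteforce <- function(traj) {
  f <- traj$frames
  span <- f[length(f)] - f[1L]
  taus <- c(); values <- c(); counts <- c()
  for (k in seq_len(span)) {
    sq <- c()
    for (i in seq_along(f)) {
      j <- which(f == f[i] + k)
      if (length(j) == 1L) {
        sq <- c(sq, (traj$x[j] - traj$x[i])^2 + (traj$y[j] - traj$y[i])^2)
      }
    }
    if (length(sq)) {
      taus <- c(taus, k * traj$dt)
      values <- c(values, mean(sq))
      counts <- c(counts, length(sq))
    }
  }
  list(taus = taus, values = values, counts = counts)
}

# random short trajectory, optionally with missing frames (tracking gaps)
random_gappy_traj <- function(n = 12, dt = 0.5, gaps = TRUE) {
  frames <- 0:(n - 1L)
  if (gaps && n > 6L) {
    drop <- sample(2:(n - 1L), size = sample(0:2, 1L))
    frames <- setdiff(frames, drop)
  }
  m <- length(frames)
  trajectory(stats::rnorm(m), stats::rnorm(m), dt = dt, frames = frames,
             id = "rand")
}
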
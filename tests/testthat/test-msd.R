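test_that("time-averaged MSD reproduces a hand-summed example", {
  tr <- trajectory(c(0, 1, 1, 2), c(0, 0, 1, 1), dt = 1)
  cv <- time_averaged_msd(tr)
  expect_equal(cv$taus, c(1, 2, 3))
  expect_equal(cv$values, c(1, 2, 5))
  expect_equal(cv$counts, c(3L, 2L, 1L))
})

test_that("a stationary trajectory has zero MSD at every lag", {
  cv <- time_averaged_msd(stationary_traj(n = 20))
  expect_true(all(cv$values == 0))
})

test_that("time-averaged MSD matches the brute-force double loop", {
  set.seed(31)
  for (i in 1:20) {
    tr <- random_gappy_traj(n = sample(6:15, 1L))
    cv <- time_averaged_msd(tr)
    ref <- msd_bruteforce(tr)
    expect_equal(cv$taus, ref$taus)
    expect_equal(cv$values, ref$values)
    expect_equal(cv$counts, ref$counts)
  }
})

test_that("gaps are respected: missing frames produce true frame lags", {
  # frames 0,1,3: lag 1 pairs (0,1) only; lag 2 pair (1,3); lag 3 pair (0,3)
  tr <- trajectory(c(0, 1, 4), c(0, 0, 0), dt = 1, frames = c(0L, 1L, 3L))
  cv <- time_averaged_msd(tr)
  expect_equal(cv$taus, c(1, 2, 3))
  expect_equal(cv$values, c(1, 9, 16))
  expect_equal(cv$counts, c(1L, 1L, 1L))
})

test_that("Brownian MSD follows 4*D*tau", {
  # single-trajectory TA-MSDs fluctuate (and are correlated across lags);
  # averaging a handful of trajectories brings the ratio within 10%
  ratios <- sapply(1:8, function(s) {
    cv <- time_averaged_msd(brownian_traj(D = 3, n = 1000, dt = 0.02,
                                          seed = 170 + s))
    cv$values[1:10] / cv$taus[1:10]
  })
  expect_equal(rowMeans(ratios), rep(12, 10), tolerance = 0.1)
})

test_that("MSD is invariant under rotation and translation", {
  tr <- brownian_traj(n = 200, seed = 23)
  th <- 0.7
  rot <- trajectory(
    cos(th) * tr$x - sin(th) * tr$y + 5,
    sin(th) * tr$x + cos(th) * tr$y - 3,
    dt = tr$dt
  )
  expect_equal(time_averaged_msd(rot)$values, time_averaged_msd(tr)$values,
               tolerance = 1e-10)
})

test_that("ensemble MSD averages per-trajectory curves", {
  c1 <- msd_curve(taus = 1:2, values = c(2, 4), counts = c(5L, 4L), dt = 1)
  c2 <- msd_curve(taus = 1:3, values = c(4, 6, 8), counts = c(5L, 4L, 3L),
                  dt = 1)
  em <- ensemble_msd(list(c1, c2))
  expect_equal(em$values, c(3, 5, 8))
  expect_equal(em$counts, c(2L, 2L, 1L))
  expect_equal(ensemble_msd(list(c1))$values, c1$values)
  expect_error(ensemble_msd(list()), "at least one")
})

test_that("ensemble and pooled averages agree for equal-length tracks", {
  set.seed(41)
  ens <- brownian_ensemble(D = 1, n_traj = 10, n = 50, seed = 41)
  em <- ensemble_msd(ens)
  # direct pooled average over all displacement pairs at lag k
  for (k in c(1L, 5L)) {
    pooled <- unlist(lapply(ens$trajectories, function(t) {
      n <- traj_length(t)
      i1 <- seq_len(n - k)
      (t$x[i1 + k] - t$x[i1])^2 + (t$y[i1 + k] - t$y[i1])^2
    }))
    expect_equal(em$values[k], mean(pooled))
  }
})

test_that("ensemble MSD of a matched Brownian ensemble equals 4*D*tau", {
  ens <- matched_brownian_ensemble(3, rep(200L, 100), 0.02, seed = 55)
  em <- ensemble_msd(ens)
  expect_equal(em$values[1:10], 4 * 3 * em$taus[1:10], tolerance = 0.05)
})

test_that("noiseless model curves are recovered exactly", {
  taus <- 1:8
  f <- fit_msd(msd_curve(taus, 4 * taus, rep(10L, 8), dt = 1), "normal",
               lag_range = c(1, 8))
  expect_equal(unname(coef(f)["D"]), 1, tolerance = 1e-8)
  expect_lt(f$fit_error, 1e-12)

  f <- fit_msd(msd_curve(taus, 4 * taus + (0.5 * taus)^2, rep(10L, 8),
                         dt = 1), "active", lag_range = c(1, 8))
  expect_equal(unname(coef(f)["D"]), 1, tolerance = 1e-8)
  expect_equal(unname(coef(f)["v"]), 0.5, tolerance = 1e-8)

  f <- fit_msd(msd_curve(taus, 4 * 0.5 * taus^0.6, rep(10L, 8), dt = 1),
               "anomalous", lag_range = c(1, 8))
  expect_equal(unname(coef(f)["alpha"]), 0.6, tolerance = 1e-4)
  expect_equal(unname(coef(f)["D"]), 0.5, tolerance = 1e-4)

  r_c <- 0.2; A1 <- 0.9; D <- 0.02; A2 <- 1 / A1
  tt <- taus * 0.1
  vals <- r_c^2 * (1 - A1 * exp(-4 * A2 * D * tt / r_c^2))
  f <- fit_msd(msd_curve(tt, vals, rep(10L, 8), dt = 0.1), "confined",
               lag_range = c(1, 8))
  expect_equal(unname(coef(f)["r_c"]), r_c, tolerance = 1e-3)
  expect_equal(unname(coef(f)["A1"]), A1, tolerance = 1e-2)
  expect_equal(unname(coef(f)["D"]), D, tolerance = 1e-2)
})

test_that("fitted parameters respect their physical bounds", {
  set.seed(61)
  for (i in 1:20) {
    tr <- random_gappy_traj(n = 30, gaps = FALSE)
    cv <- time_averaged_msd(tr)
    for (model in transport_modes()) {
      mdl <- switch(model, normal = "normal", active = "active",
                    anomalous = "anomalous", confined = "confined")
      f <- fit_msd(cv, mdl)
      if (is.finite(f$D)) expect_gte(f$D, 0)  # NA only on flagged fits
      if (!f$converged) expect_false(is.null(f$fit_error))
      expect_gte(f$fit_error, 0)
      if (mdl == "anomalous") {
        expect_true(f$alpha >= 0.1 && f$alpha <= 2)
      }
      if (mdl == "confined" && f$converged) {
        expect_true(f$A1 > 0 && f$A1 <= 2)
        expect_gt(f$A2, 0)
      }
    }
  }
})

test_that("degenerate all-zero curves yield flagged fits, not errors", {
  cv <- time_averaged_msd(stationary_traj(n = 20))
  fa <- fit_msd(cv, "anomalous")
  expect_false(fa$converged)
  expect_equal(fa$D, 0)
  fc <- fit_msd(cv, "confined")
  expect_false(fc$converged)
})

test_that("too-narrow lag ranges are rejected", {
  cv <- msd_curve(1:3, c(4, 8, 12), rep(5L, 3), dt = 1)
  expect_error(fit_msd(cv, "normal", lag_range = c(1, 2)), "at least 3")
  expect_error(fit_msd(cv, "confined", lag_range = c(1, 3)), "at least 4")
})

test_that("localization noise biases short-lag alpha downward, monotonically", {
  alphas <- vapply(c(0, 0.02, 0.05), function(sig) {
    ens <- lapply(1:40, function(i) {
      simulate_trajectory(
        sim_config("normal", D = 0.01, n_steps = 300, dt = 0.02,
                   sigma_loc = sig, seed = 1000 + i),
        id = paste0("n", i)
      )
    })
    mean(per_trajectory_anomaly(traj_ensemble(ens))$alpha)
  }, numeric(1))
  expect_true(all(diff(alphas) < 0))
  expect_lt(alphas[3], 1)
})

test_that("predict, residuals and simulate methods are consistent", {
  taus <- 1:6
  f <- fit_msd(msd_curve(taus, 4 * 2 * taus, rep(10L, 6), dt = 1), "normal",
               lag_range = c(1, 6))
  expect_equal(predict(f), fitted(f))
  expect_equal(residuals(f), f$values - f$fitted)
  expect_equal(predict(f, taus = 10), 80, tolerance = 1e-8)
  sims <- simulate(f, nsim = 3, seed = 2, n_steps = 50)
  expect_length(sims$trajectories, 3L)
  expect_true(all(vapply(sims$trajectories, traj_length, integer(1)) == 50L))
})
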
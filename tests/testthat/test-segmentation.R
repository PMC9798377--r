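test_that("segmentation config enforces the window/segment relations", {
  cfg <- segmentation_config(window_s = 1)
  expect_equal(cfg$min_segment_s, 0.6)
  expect_error(segmentation_config(window_s = 0), "positive")
  expect_error(segmentation_config(window_s = 1, min_segment_s = 2),
               "min_segment_s")
  expect_error(segmentation_config(window_s = 1, alpha_sub = 1.1), "alpha")
})

test_that("windows of pure strong-signal motion classify correctly", {
  dt <- 0.05
  cfg <- segmentation_config(window_s = 2)
  L <- 41L
  # noiseless linear MSD window: ballistic-free Brownian path
  tr <- simulate_trajectory(sim_config("normal", D = 0.05, n_steps = L,
                                       dt = dt, seed = 12))
  expect_type(as.character(classify_window(tr, cfg)), "character")
  # strong active window: v*T >> sqrt(4*D*T)
  act <- simulate_trajectory(sim_config("active", D = 0.001, v = 1,
                                        n_steps = L, dt = dt, seed = 13))
  expect_equal(as.character(classify_window(act, cfg)), "active")
  # deep confinement: r_c << sqrt(4*D*window)
  conf <- simulate_trajectory(sim_config("confined", D = 0.2, r_c = 0.08,
                                         n_steps = L, dt = dt, seed = 14))
  expect_equal(as.character(classify_window(conf, cfg)), "confined")
  # degenerate window: no measurable displacement
  expect_equal(as.character(classify_window(stationary_traj(n = L, dt = dt),
                                            cfg)), "confined")
})

test_that("pure Brownian trajectories are labelled normal nearly everywhere", {
  dt <- 0.05
  cfg <- segmentation_config(window_s = 2)
  fracs <- vapply(1:5, function(s) {
    tr <- simulate_trajectory(sim_config("normal", D = 0.05, n_steps = 500,
                                         dt = dt, seed = 300 + s))
    sc <- rolling_classify(tr, cfg)
    mean(sc$labels == "normal")
  }, numeric(1))
  expect_gte(mean(fracs), 0.9)
})

test_that("segments partition the trajectory and respect the minimum length", {
  dt <- 0.05
  cfg <- segmentation_config(window_s = 2)
  tr <- simulate_switching(list(
    list(config = sim_config("normal", D = 0.05, n_steps = 2, dt = dt),
         duration_s = 15),
    list(config = sim_config("active", D = 0.005, v = 1, n_steps = 2,
                             dt = dt), duration_s = 15)
  ), seed = 21)
  sc <- rolling_classify(tr, cfg)
  seg <- sc$segments
  # coverage without gaps or overlaps
  expect_equal(seg$start_frame[1], tr$frames[1])
  expect_equal(seg$end_frame[nrow(seg)], tr$frames[length(tr$frames)])
  if (nrow(seg) > 1) {
    expect_true(all(seg$start_frame[-1] == seg$end_frame[-nrow(seg)] + 1L))
  }
  expect_equal(sum(seg$n_positions), traj_length(tr))
  # minimum segment duration (single-run trajectories exempt)
  if (nrow(seg) > 1) {
    expect_true(all(seg$duration_s >= cfg$min_segment_s - 1e-9))
  }
})

test_that("a trajectory exactly one window long yields a single segment", {
  dt <- 0.05
  cfg <- segmentation_config(window_s = 2)
  tr <- simulate_trajectory(sim_config("normal", D = 0.05, n_steps = 41,
                                       dt = dt, seed = 33))
  sc <- rolling_classify(tr, cfg)
  expect_equal(nrow(sc$segments), 1L)
  expect_equal(sc$segments$n_positions, 41L)
})

test_that("trajectories shorter than the window are flagged, not classified", {
  tr <- brownian_traj(n = 20, dt = 0.05, seed = 2)
  cfg <- segmentation_config(window_s = 2)
  expect_warning(sc <- rolling_classify(tr, cfg), "shorter")
  expect_equal(nrow(sc$segments), 0L)
  expect_true(all(is.na(sc$labels)))
})

test_that("switching trajectories are segmented near the true switch point", {
  dt <- 0.05
  w <- 2
  cfg <- segmentation_config(window_s = w)
  hits <- 0L; total <- 0L
  for (s in 1:4) {
    tr <- simulate_switching(list(
      list(config = sim_config("normal", D = 0.05, n_steps = 2, dt = dt),
           duration_s = 20),
      list(config = sim_config("active", D = 0.005, v = 1, n_steps = 2,
                               dt = dt), duration_s = 20)
    ), seed = 500 + s)
    sc <- rolling_classify(tr, cfg)
    # compare the onset of detected active motion with the true switch
    true_sw <- which(diff(tr$labels == "active") != 0)
    det_sw <- which(diff(sc$labels == "active") != 0)
    total <- total + 1L
    if (length(det_sw) && min(abs(det_sw - true_sw)) * dt <= w) {
      hits <- hits + 1L
    }
  }
  expect_equal(hits, total)
})

test_that("segment parameter refits recover the generating values", {
  dt <- 0.05
  mk_seg <- function(tr, mode, n) {
    data.frame(traj_id = tr$id, start_frame = 0L, end_frame = n - 1L,
               mode = mode, D = NA_real_, v = NA_real_, alpha = NA_real_,
               duration_s = (n - 1L) * dt, n_positions = n,
               stringsAsFactors = FALSE)
  }
  v_err <- vapply(1:50, function(s) {
    tr <- simulate_trajectory(sim_config("active", D = 0.001, v = 0.1,
                                         n_steps = 300, dt = dt,
                                         seed = 700 + s))
    abs(segment_parameters(mk_seg(tr, "active", 300L), tr)$v - 0.1) / 0.1
  }, numeric(1))
  expect_lt(stats::median(v_err), 0.1)
  d_err <- vapply(1:50, function(s) {
    tr <- simulate_trajectory(sim_config("normal", D = 0.002, n_steps = 300,
                                         dt = dt, seed = 800 + s))
    abs(segment_parameters(mk_seg(tr, "normal", 300L), tr)$D - 0.002) /
      0.002
  }, numeric(1))
  expect_lt(stats::median(d_err), 0.15)
  # stationary segment: D collapses to zero
  st <- stationary_traj(n = 50)
  seg <- data.frame(traj_id = st$id, start_frame = 0L, end_frame = 49L,
                    mode = "normal", D = NA_real_, v = NA_real_,
                    alpha = NA_real_, duration_s = 49, n_positions = 50L,
                    stringsAsFactors = FALSE)
  expect_equal(segment_parameters(seg, st)$D, 0)
})

test_that("mode proportions are position-weighted and normalized", {
  seg <- data.frame(
    traj_id = "t", start_frame = c(0L, 60L), end_frame = c(59L, 99L),
    mode = c("normal", "active"), D = c(0.01, 0.02), v = c(NA, 0.3),
    alpha = c(NA, NA), duration_s = c(5.9, 3.9), n_positions = c(60L, 40L),
    stringsAsFactors = FALSE
  )
  st <- mode_proportions(seg)
  expect_equal(sum(st$mode_proportions), 1, tolerance = 1e-9)
  expect_equal(unname(st$mode_proportions["normal"]), 0.6)
  expect_equal(unname(st$mode_proportions["active"]), 0.4)
  expect_equal(st$velocity_distribution, 0.3)
  # single all-normal trajectory
  st1 <- mode_proportions(seg[1, ])
  expect_equal(unname(st1$mode_proportions), c(1, 0, 0, 0))
})

test_that("switching ensembles recover the planted active proportion", {
  dt <- 0.05
  ens <- traj_ensemble(lapply(1:6, function(i) {
    simulate_switching(list(
      list(config = sim_config("normal", D = 0.05, n_steps = 2, dt = dt),
           duration_s = 24),
      list(config = sim_config("active", D = 0.005, v = 1, n_steps = 2,
                               dt = dt), duration_s = 6)
    ), seed = 900 + i, id = paste0("sw", i))
  }))
  seg <- segment_ensemble(ens, segmentation_config(window_s = 2))
  st <- mode_proportions(seg)
  expect_equal(unname(st$mode_proportions["active"]), 0.2, tolerance = 0.25)
  expect_equal(sum(st$mode_proportions), 1, tolerance = 1e-9)
})

test_that("rapid-transport fraction counts fast active segments", {
  seg <- data.frame(
    traj_id = "t", start_frame = c(0L, 10L, 20L, 30L),
    end_frame = c(9L, 19L, 29L, 39L),
    mode = c("active", "active", "active", "normal"),
    D = c(0.02, 0.002, 0.03, 0.5), v = c(0.1, 0.05, 0.2, NA),
    alpha = rep(NA_real_, 4), duration_s = rep(1, 4),
    n_positions = rep(10L, 4), stringsAsFactors = FALSE
  )
  expect_equal(rapid_transport_fraction(seg), 2 / 3)
  expect_equal(rapid_transport_fraction(seg, cutoff_D = 0), 1)
  expect_equal(rapid_transport_fraction(seg, cutoff_D = 1), 0)
  expect_warning(f <- rapid_transport_fraction(seg[4, ]), "no active")
  expect_true(is.na(f))
})

test_that("median segment length grows with the analysis window", {
  dt <- 0.05
  ens <- traj_ensemble(lapply(1:6, function(i) {
    simulate_switching(list(
      list(config = sim_config("normal", D = 0.05, n_steps = 2, dt = dt),
           duration_s = 12),
      list(config = sim_config("active", D = 0.005, v = 1, n_steps = 2,
                               dt = dt), duration_s = 6),
      list(config = sim_config("normal", D = 0.05, n_steps = 2, dt = dt),
           duration_s = 12),
      list(config = sim_config("active", D = 0.005, v = 1, n_steps = 2,
                               dt = dt), duration_s = 6)
    ), seed = 40 + i, id = paste0("sw", i))
  }))
  med_len <- vapply(c(1, 2, 4), function(w) {
    seg <- segment_ensemble(ens, segmentation_config(window_s = w))
    stats::median(seg$segments$duration_s)
  }, numeric(1))
  expect_true(all(diff(med_len) >= 0))
})
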
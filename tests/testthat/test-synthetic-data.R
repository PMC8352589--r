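test_that("sim_config validates physical parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(D_bound = 1, D_free = 0.5), "smaller")
  expect_error(sim_config(D_free = 200, nucleus_radius = 1), "non-physical")
  expect_error(sim_config(sigma_loc = -1), "positive")
  expect_error(sim_config(n_trajectories = 0), "positive")
})

test_that("trajectory simulation is deterministic and internally consistent", {
  cfg <- sim_config(n_trajectories = 100, seed = 42)
  a <- simulate_two_state_trajectories(cfg)
  b <- simulate_two_state_trajectories(cfg)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$ground_truth, b$ground_truth)
  # one state label per observed displacement
  n_disp <- a$trajectories |>
    dplyr::count(track_id) |>
    dplyr::summarise(n = sum(n - 1L)) |>
    dplyr::pull(n)
  expect_equal(nrow(a$ground_truth), n_disp)
})

test_that("absorbing bound state never produces free displacements", {
  cfg <- sim_config(k_off_state = 0, k_on_state = 5,
                    n_trajectories = 200, seed = 7)
  sim <- simulate_two_state_trajectories(cfg)
  expect_true(all(sim$ground_truth$state == "bound"))
})

test_that("symmetric switching gives a half-bound stationary fraction", {
  cfg <- sim_config(k_off_state = 10, k_on_state = 10, dZ = Inf,
                    nucleus_radius = 20, n_frames_mean = 40,
                    n_trajectories = 1500, seed = 3)
  sim <- simulate_two_state_trajectories(cfg)
  frac <- mean(sim$ground_truth$state == "bound")
  expect_lt(abs(frac - 0.5), 0.03)
})

test_that("bound-state step lengths follow the Rayleigh law", {
  cfg <- sim_config(D_bound = 0.05, D_free = 1, k_off_state = 0,
                    k_on_state = 1, sigma_loc = 0.025, dZ = Inf,
                    nucleus_radius = 50, n_frames_mean = 25,
                    n_trajectories = 600, seed = 11)
  sim <- simulate_two_state_trajectories(cfg)
  steps <- sim$trajectories |>
    dplyr::group_by(track_id) |>
    dplyr::reframe(r = sqrt(diff(x_um)^2 + diff(y_um)^2)) |>
    dplyr::pull(r)
  steps <- steps[seq_len(min(10000, length(steps)))]
  scale2 <- 2 * (cfg$D_bound * cfg$frame_interval + cfg$sigma_loc^2)
  ks <- stats::ks.test(steps, function(q) 1 - exp(-q^2 / (2 * scale2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("without slab or boundary the generator keeps full track lengths", {
  cfg <- sim_config(dZ = Inf, nucleus_radius = 100, n_frames_mean = 20,
                    n_trajectories = 2000, seed = 9)
  sim <- simulate_two_state_trajectories(cfg)
  mean_len <- sim$trajectories |>
    dplyr::count(track_id) |>
    dplyr::summarise(m = mean(n)) |>
    dplyr::pull(m)
  # geometric with mean 20, floored at 2 localizations
  expect_lt(abs(mean_len - 20) / 20, 0.1)
  # with the slab on, free molecules are lost early and tracks shorten
  cfg2 <- sim_config(dZ = 0.6, nucleus_radius = 100, n_frames_mean = 20,
                     n_trajectories = 2000, seed = 9)
  sim2 <- simulate_two_state_trajectories(cfg2)
  mean_len2 <- sim2$trajectories |>
    dplyr::count(track_id) |>
    dplyr::summarise(m = mean(n)) |>
    dplyr::pull(m)
  expect_lt(mean_len2, mean_len)
})

test_that("dwell-event mixture has the analytic mean duration", {
  f_sb <- 0.3; k_sb <- 0.2; k_tb <- 2
  ev <- simulate_dwell_events(f_sb, k_sb, k_tb, k_bleach = 0, n = 20000,
                              seed = 2)
  mu <- f_sb / k_sb + (1 - f_sb) / k_tb
  # mixture variance for the 3-s.e. band
  m2 <- 2 * (f_sb / k_sb^2 + (1 - f_sb) / k_tb^2)
  se <- sqrt((m2 - mu^2) / nrow(ev))
  expect_lt(abs(mean(ev$true_s) - mu), 3 * se)
  # pure-exponential limit
  ev1 <- simulate_dwell_events(1, 0.25, 10, k_bleach = 0, n = 20000, seed = 3)
  expect_lt(abs(mean(ev1$true_s) - 4), 3 * 4 / sqrt(20000))
})

test_that("dwell events respect bleaching, quantization and validation", {
  ev <- simulate_dwell_events(0.5, 0.2, 2, k_bleach = 1e6, n = 500, seed = 1)
  expect_true(all(ev$dwell_s == 0.25))  # everything collapses to one frame
  ev2 <- simulate_dwell_events(0.5, 0.2, 2, n = 500, seed = 1)
  expect_true(all(ev2$dwell_s %% 0.25 == 0))
  expect_true(all(ev2$dwell_s >= ev2$true_s))
  expect_error(simulate_dwell_events(0.5, 2, 0.2, n = 10), "smaller")
  expect_identical(simulate_dwell_events(0.5, 0.2, 2, n = 50, seed = 8),
                   simulate_dwell_events(0.5, 0.2, 2, n = 50, seed = 8))
})

test_that("reference standard is a single exponential with the requested rate", {
  ref <- simulate_reference_standard(0.1, n = 10000, seed = 4)
  k_hat <- reference_rate(ref)
  expect_lt(abs(k_hat - 0.1) / 0.1, 0.05)
  # rate doubling halves the mean
  ref2 <- simulate_reference_standard(0.2, n = 10000, seed = 4)
  ratio <- mean(ref2$dwell_s) / mean(ref$dwell_s)
  expect_lt(abs(ratio - 0.5), 0.05)
  expect_identical(simulate_reference_standard(0.1, n = 100, seed = 6),
                   simulate_reference_standard(0.1, n = 100, seed = 6))
})
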
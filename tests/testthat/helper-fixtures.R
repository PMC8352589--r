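# shared fixtures and independent oracles, built in code at test time

# a straight-line trajectory with constant step length (ballistic)
ballistic_track <- function(n = 10, step = 0.1, track_id = 1L) {
  tibble::tibble(track_id = track_id, frame = 0:(n - 1),
                 x_um = step * (0:(n - 1)), y_um = 0)
}

# pure random-walk trajectories, generated independently of the package
# simulator (oracle for MSD-based D estimation)
random_walk_tracks <- function(n_tracks, n_frames, D, dt = 0.01,
                               sigma = 0.001, seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_tracks), function(i) {
      x <- cumsum(c(0, rnorm(n_frames - 1, sd = sqrt(2 * D * dt))))
      y <- cumsum(c(0, rnorm(n_frames - 1, sd = sqrt(2 * D * dt))))
      tibble::tibble(track_id = i, frame = 0:(n_frames - 1),
                     x_um = x + rnorm(n_frames, sd = sigma),
                     y_um = y + rnorm(n_frames, sd = sigma))
    })
  })
}

# exact MSD curve of the circular confinement model
confinement_curve <- function(Rc, D, n_points = 10, dt = 0.01,
                              track_id = 1L) {
  t <- dt * seq_len(n_points)
  tibble::tibble(track_id = track_id, lag = seq_len(n_points), time_s = t,
                 msd = Rc^2 * (1 - exp(-4 * D * t / Rc^2)),
                 n_pairs = 100L)
}

# Monte-Carlo oracle for slab survival with continuously absorbing
# boundaries: discrete steps plus Brownian-bridge boundary-crossing
# probabilities per step, which removes the time-discretization bias
mc_slab_survival <- function(D, t, dZ, n = 1e5, dt = 1e-3, seed = 1) {
  withr::with_seed(seed, {
    half <- dZ / 2
    z <- runif(n, -half, half)
    alive <- rep(TRUE, n)
    for (i in seq_len(round(t / dt))) {
      z_new <- z + rnorm(n, sd = sqrt(2 * D * dt))
      out <- abs(z_new) > half
      inside <- alive & !out
      # bridge crossing probability for walkers inside at both endpoints
      p_top <- exp(-pmax(0, (half - z[inside]) * (half - z_new[inside])) / (D * dt))
      p_bot <- exp(-pmax(0, (half + z[inside]) * (half + z_new[inside])) / (D * dt))
      crossed <- runif(sum(inside)) < (p_top + p_bot - p_top * p_bot)
      alive[alive & out] <- FALSE
      alive[inside][crossed] <- FALSE
      z <- z_new
    }
    mean(alive)
  })
}

# standard two-state simulation used by several HMM tests
hmm_fixture <- function(n_traj = 800, seed = 5, k_off = 10, k_on = 10,
                        D_bound = 0.03, D_free = 1.0, sigma = 0.002) {
  simulate_two_state_trajectories(sim_config(
    D_bound = D_bound, D_free = D_free, k_off_state = k_off,
    k_on_state = k_on, sigma_loc = sigma, nucleus_radius = 5, dZ = Inf,
    n_frames_mean = 30, n_trajectories = n_traj, seed = seed))
}

label_accuracy <- function(sim, model) {
  lab <- classify_displacements(model, sim$trajectories)
  merged <- dplyr::inner_join(lab, sim$ground_truth, by = c("track_id", "step"),
                              suffix = c("_hat", "_true"))
  mean(merged$state_hat == merged$state_true)
}
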
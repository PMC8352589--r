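test_that("jump collection caps per-trajectory jumps and the max jump", {
  tr <- ballistic_track(n = 7, step = 0.05)
  jd <- build_jump_length_data(tr, n_timepoints = 2)
  expect_equal(sum(jd$jumps$lag == 1), 4L)  # min(6, 4) jumps at lag 1
  expect_equal(sum(jd$jumps$lag == 2), 4L)

  big <- ballistic_track(n = 5, step = 2.5)  # every jump beyond 2 um
  jd2 <- build_jump_length_data(big, n_timepoints = 2)
  expect_equal(nrow(jd2$jumps), 0L)

  # empirical CDF reaches 1 at the max jump
  sim <- hmm_fixture(n_traj = 100, seed = 31)
  jd3 <- build_jump_length_data(sim$trajectories)
  top <- jd3$cdf |> dplyr::filter(r_um == max(r_um))
  expect_true(all(top$cdf == 1))
  expect_error(build_jump_length_data(sim$trajectories[0, ]), "empty")
})

test_that("model jump CDF collapses to a Rayleigh when fully bound", {
  r <- seq(0, 1, 0.01)
  got <- model_jump_cdf(r, lag_time = 0.02, F_bound = 1, D_bound = 0.05,
                        D_free = 1, sigma = 0.025)
  s2 <- 2 * (0.05 * 0.02 + 0.025^2)
  expect_equal(got, 1 - exp(-r^2 / (2 * s2)), tolerance = 1e-12)
})

test_that("model jump CDF median matches a Monte-Carlo quadrature oracle", {
  D <- 0.08; t <- 0.03; sig <- 0.02
  med_model <- stats::uniroot(function(r) {
    model_jump_cdf(r, t, 1, D, 1, sig) - 0.5
  }, c(1e-4, 2))$root
  withr::with_seed(17, {
    xy <- matrix(rnorm(2e5 * 2, sd = sqrt(2 * (D * t + sig^2))), ncol = 2)
    med_mc <- median(sqrt(rowSums(xy^2)))
  })
  expect_lt(abs(med_model - med_mc) / med_mc, 0.01)
})

test_that("model jump CDF is monotone for random admissible parameters", {
  withr::with_seed(23, {
    for (i in 1:20) {
      F_b <- runif(1)
      D_b <- 10^runif(1, log10(5e-4), log10(0.1))
      D_f <- 10^runif(1, log10(0.15), log10(25))
      sig <- runif(1, 0.01, 0.1)
      lag <- sample(1:6, 1) * 0.01
      v <- model_jump_cdf(seq(0, 2, 0.01), lag, F_b, D_b, D_f, sig)
      expect_true(all(diff(v) >= -1e-12))
      expect_true(all(v >= 0 & v <= 1 + 1e-12))
    }
  })
})

test_that("defocalization fraction has the right limits and MC agreement", {
  expect_equal(defocalization_fraction(0, 0.05, 0.6), 1)
  expect_equal(defocalization_fraction(1, 0, 0.6), 1)
  expect_equal(defocalization_fraction(1, 0.05, Inf), 1)
  expect_gt(defocalization_fraction(1, 0.05, 1000), 0.999)
  # spot check against the bridge-corrected Monte-Carlo oracle
  got <- defocalization_fraction(1, 0.05, 0.6)
  mc <- mc_slab_survival(1, 0.05, 0.6, n = 1e5, seed = 2)
  expect_lt(abs(got - mc), 0.005)
})

test_that("frame-sampled slab survival dominates the absorbing-slab survival", {
  D <- 1; dt <- 0.01; dZ <- 0.6
  sam <- sampled_slab_survival(D, 1:8, dZ, dt)
  cont <- defocalization_fraction(D, (1:8) * dt, dZ)
  expect_true(all(diff(sam) < 0))        # monotone decreasing in frames
  expect_true(all(sam > cont))           # frame sampling loses fewer molecules
  expect_equal(sampled_slab_survival(D, 1:3, Inf, dt), rep(1, 3))
})

test_that("two-state fit recovers a single bound state", {
  cfg <- sim_config(D_bound = 0.05, D_free = 1, k_off_state = 0,
                    k_on_state = 5, sigma_loc = 0.025, nucleus_radius = 5,
                    n_trajectories = 1500, seed = 19)
  sim <- simulate_two_state_trajectories(cfg)
  fit <- fit_two_state(build_jump_length_data(sim$trajectories), seed = 2)
  expect_gte(fit$estimate$F_bound, 0.95)
  expect_lt(abs(fit$estimate$D_bound - 0.05) / 0.05, 0.10)
  # parameters respect the declared bounds
  expect_true(fit$estimate$D_bound >= 5e-4 && fit$estimate$D_bound <= 0.1)
  expect_true(fit$estimate$D_free >= 0.15 && fit$estimate$D_free <= 25)
  expect_true(fit$estimate$sigma >= 0.01 && fit$estimate$sigma <= 0.1)
  expect_true(fit$estimate$F_bound >= 0 && fit$estimate$F_bound <= 1)
})

test_that("dropping the Z correction biases the bound fraction upward", {
  cfg <- sim_config(D_bound = 0.05, D_free = 1, k_off_state = 0.9,
                    k_on_state = 1.1, sigma_loc = 0.025, nucleus_radius = 5,
                    dZ = 0.6, n_trajectories = 2000, seed = 29)
  sim <- simulate_two_state_trajectories(cfg)
  jd <- build_jump_length_data(sim$trajectories)
  with_z <- fit_two_state(jd, dZ = 0.6, seed = 2)
  no_z <- fit_two_state(jd, dZ = Inf, seed = 2)
  expect_gt(no_z$estimate$F_bound, with_z$estimate$F_bound)
})
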
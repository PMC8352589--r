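test_that("MSD is exact for ballistic and static trajectories", {
  msd <- compute_msd(ballistic_track(n = 10, step = 0.1), max_lag = 5)
  expect_equal(msd$msd, (0.1 * msd$lag)^2, tolerance = 1e-12)

  static <- tibble::tibble(track_id = 1, frame = 0:9, x_um = 0.3, y_um = -0.2)
  expect_true(all(compute_msd(static, max_lag = 5)$msd == 0))

  three <- ballistic_track(n = 3)
  out <- compute_msd(three, max_lag = 2)
  expect_equal(out$n_pairs[out$lag == 2], 1L)
  expect_error(compute_msd(three, max_lag = 3), "smaller")
})

test_that("MSD is invariant under translation and rotation", {
  tr <- random_walk_tracks(1, 20, D = 0.5, seed = 8)
  th <- 0.7
  rot <- tr |>
    dplyr::mutate(x2 = cos(th) * x_um - sin(th) * y_um + 5,
                  y2 = sin(th) * x_um + cos(th) * y_um - 3) |>
    dplyr::mutate(x_um = x2, y_um = y2) |>
    dplyr::select(track_id, frame, x_um, y_um)
  expect_equal(compute_msd(tr, max_lag = 5)$msd,
               compute_msd(rot, max_lag = 5)$msd, tolerance = 1e-10)
})

test_that("linear MSD fit recovers D = slope / 4 and applies the R^2 filter", {
  exact <- function(D) tibble::tibble(track_id = 1, lag = 1:5,
                                      time_s = 0.01 * (1:5),
                                      msd = 4 * D * 0.01 * (1:5), n_pairs = 50L)
  # suppressed warning: lm flags the zero-residual fit as "essentially perfect"
  expect_equal(suppressWarnings(fit_diffusion_coefficient(exact(0.026)))$D,
               0.026, tolerance = 1e-10)
  expect_equal(suppressWarnings(fit_diffusion_coefficient(exact(5)))$D, 5,
               tolerance = 1e-10)

  noisy <- tibble::tibble(track_id = 1, lag = 1:5, time_s = 0.01 * (1:5),
                          msd = c(0.02, 0.005, 0.03, 0.004, 0.05),
                          n_pairs = 50L)
  fit <- fit_diffusion_coefficient(noisy)
  expect_false(fit$accepted)
  expect_lt(fit$r_squared, 0.8)
})

test_that("median fitted D is within 10% of truth for free diffusion", {
  D <- 0.5
  tracks <- random_walk_tracks(1000, 20, D = D, seed = 13)
  fits <- compute_msd(tracks, max_lag = 5) |> fit_diffusion_coefficient()
  med <- median(fits$D[fits$accepted])
  expect_lt(abs(med - D) / D, 0.1)
})

test_that("log10 D mixture recovers two synthetic populations", {
  withr::with_seed(5, {
    D_vals <- 10^c(rnorm(400, -1.5, 0.2), rnorm(400, 0, 0.2))
  })
  fit <- fit_log10D_mixture(D_vals)
  expect_s3_class(fit, "gmm_fit")
  expect_lt(abs(fit$components$mean[1] - (-1.5)), 0.1)
  expect_lt(abs(fit$components$mean[2] - 0), 0.1)
  expect_equal(sum(fit$components$weight), 1, tolerance = 1e-8)
  expect_false(fit$degenerate)
  expect_equal(tidy(fit), fit$components)

  withr::with_seed(6, single <- 10^rnorm(300, -1, 0.2))
  fit1 <- fit_log10D_mixture(single)
  expect_true(fit1$degenerate)
  expect_error(fit_log10D_mixture(rep(0.5, 10)), "distinct")
})

test_that("confinement fit recovers parameters from an exact model curve", {
  fit <- fit_confinement(confinement_curve(Rc = 0.15, D = 0.05))
  expect_true(fit$accepted)
  expect_lt(abs(fit$Rc - 0.15) / 0.15, 0.01)
  expect_lt(abs(fit$D_short - 0.05) / 0.05, 0.01)
  # plateau of the fitted model is Rc^2
  expect_equal(fit$Rc^2, 0.15^2, tolerance = 0.01)
})

test_that("confinement filters reject large radii and non-confined curves", {
  big <- fit_confinement(confinement_curve(Rc = 0.4, D = 0.05))
  expect_false(big$accepted)
  expect_equal(big$reason, "rc_above_threshold")

  # short-time expansion: (1 - exp(-x))/x deviates from 1 by ~x/2, so the
  # circular model equals 4 D t within 1% for x = 4 D t / Rc^2 <= 0.02
  Rc <- 0.2; D <- 0.05
  t <- seq(1e-4, 0.02 * Rc^2 / (4 * D), length.out = 20)
  model <- Rc^2 * (1 - exp(-4 * D * t / Rc^2))
  expect_true(all(abs(model - 4 * D * t) / (4 * D * t) < 0.01))
})
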